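# Small fixtures shared across test files; everything is generated in code.

# A featureless model: no wells, a soft wall far to the left, so the
# biased density is essentially the pure restraint Gaussian.
flatModel <- function() {
  ModelPotential(cmPos = 5, depthTQuad = c(0, 0, 0), cmWidth = 0.6,
                 wallPos = 0.5, wallScale = 0.1)
}

# Series with prescribed xi values under a nominal window/condition.
seriesFromXi <- function(xi, d0 = 5, k = 0, temperature = 298,
                         ionicStrength = 0) {
  ReactionCoordinateSeries(WindowSpec(d0, k), Condition(temperature,
                                                        ionicStrength),
                           xi = xi)
}

# An analytic noiseless PMFProfile on a regular grid.
profileFromFunction <- function(f, from, to, by = 0.1, temperature = 298,
                                ionicStrength = 0) {
  x <- seq(from + by / 2, to - by / 2, by = by)
  new("PMFProfile", binCenters = x, F = f(x), Ferr = numeric(0),
      counts = rep(1000, length(x)), windowShifts = 0,
      condition = Condition(temperature, ionicStrength),
      converged = TRUE, iterations = 1L)
}

paperTemperatures <- c(273, 285, 298, 310, 323, 335, 348, 360, 373)
paperIonicStrengths <- c(0, 0.4, 1, 1.5, 2)
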