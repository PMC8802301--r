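#' Evaluate the ground-truth model PMF
#'
#' Evaluates a \linkS4class{ModelPotential} at distances `xi` under a given
#' condition. The result is the analytic free-energy profile the synthetic
#' sampler draws from: repulsive wall + optional DM/SSM Gaussians + a CM
#' Gaussian whose amplitude is set so that the value at the CM position
#' equals the configured depth law exactly (see [cmDepth()]). The profile is
#' smooth in `xi` and tends to zero at large separation.
#'
#' @param model a \linkS4class{ModelPotential}
#' @param xi distances, Angstrom; all must exceed `model@wallPos`
#' @param condition a \linkS4class{Condition}
#' @return numeric vector of free energies, kcal/mol
#' @examples
#' m <- hexanePreset()$model
#' modelPMF(m, seq(4, 14, 0.5), Condition(298, 0))
#' @export
modelPMF <- function(model, xi, condition) {
  stopifnot(is(model, "ModelPotential"), is(condition, "Condition"))
  if (any(xi <= model@wallPos))
    stop("modelPMF: xi must exceed the wall position (",
         format(model@wallPos), " Angstrom)")
  p <- .modelParams(model, condition)
  .modelEval(p, xi)
}

## Flatten a (model, condition) pair into the numeric parameter vector shared
## with the C++ sampler: (wallPos, wallScale, cmPos, cmWidth, cmAmp,
## dmPos, dmHeight, dmWidth, ssmPos, ssmDepth, ssmWidth). Absent features
## get zero amplitude.
.modelParams <- function(model, condition) {
  dmH <- if (is.na(model@dmPos)) 0 else model@dmHeight
  dmP <- if (is.na(model@dmPos)) model@cmPos + 1 else model@dmPos
  ssmD <- if (is.na(model@ssmPos)) 0 else model@ssmDepth
  ssmP <- if (is.na(model@ssmPos)) model@cmPos + 2 else model@ssmPos
  depth <- cmDepth(model, temperature = condition@temperature,
                   ionicStrength = condition@ionicStrength)
  ## fixed (non-CM) part evaluated at the CM position
  fixedAtCM <- (model@wallScale / (model@cmPos - model@wallPos))^12 +
    dmH * exp(-(model@cmPos - dmP)^2 / (2 * model@dmWidth^2)) +
    ssmD * exp(-(model@cmPos - ssmP)^2 / (2 * model@ssmWidth^2))
  c(model@wallPos, model@wallScale, model@cmPos, model@cmWidth,
    depth - fixedAtCM, dmP, dmH, model@dmWidth, ssmP, ssmD, model@ssmWidth)
}

.modelEval <- function(p, xi) {
  (p[2] / (xi - p[1]))^12 +
    p[5] * exp(-(xi - p[3])^2 / (2 * p[4]^2)) +
    p[7] * exp(-(xi - p[6])^2 / (2 * p[8]^2)) +
    p[10] * exp(-(xi - p[9])^2 / (2 * p[11]^2))
}

#' @rdname cmDepth
#' @param temperature K
#' @param ionicStrength mol/dm^3
#' @export
setMethod("cmDepth", "ModelPotential",
  function(x, temperature, ionicStrength = 0) {
    q <- x@depthTQuad
    q[1] + q[2] * temperature + q[3] * temperature^2 +
      x@depthISSlope * ionicStrength
  })

#' Harmonic restraint (bias) energy of an umbrella window
#'
#' The restraint applied to the distance coordinate in window `window`.
#' The default convention is `V = k * (xi - d0)^2` with no 1/2 factor
#' (the convention of the MD engine family this emulates);
#' `convention = "half_k_sq"` gives `V = k/2 * (xi - d0)^2`.
#'
#' @param window a \linkS4class{WindowSpec}
#' @param xi distances, Angstrom (vectorized)
#' @param convention `"k_sq"` (default) or `"half_k_sq"`
#' @return bias energies, kcal/mol
#' @examples
#' biasEnergy(WindowSpec(4, 2), c(3, 4, 5))
#' @export
biasEnergy <- function(window, xi, convention = c("k_sq", "half_k_sq")) {
  stopifnot(is(window, "WindowSpec"))
  convention <- match.arg(convention)
  pref <- if (convention == "k_sq") 1 else 0.5
  pref * window@k * (xi - window@d0)^2
}
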