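#' @useDynLib hydrotherm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
## the caller's .Random.seed afterwards (no hidden global state).
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

#' Sample one umbrella window from the model potential
#'
#' Draws a biased reaction-coordinate time series for one window by Gaussian
#' random-walk Metropolis Monte Carlo on the 1-D coordinate, with stationary
#' density proportional to
#' `exp(-(modelPMF + biasEnergy) / (kB * T))`
#' on the interval `(wallPos, xMax]`. This is the synthetic stand-in for an
#' MD umbrella-sampling run: the chain is started at the minimum of the
#' biased potential, burnt in for `ceiling(burnFrac * nSamples)` steps with
#' step-size adaptation toward 30--50\% acceptance, then run for
#' `nSamples * thin` further steps keeping every `thin`-th. Identical seed
#' and inputs give bitwise-identical output. Times are synthetic
#' (index x 0.2 ps, the emulated save stride).
#'
#' @param model a \linkS4class{ModelPotential}
#' @param window a \linkS4class{WindowSpec}
#' @param condition a \linkS4class{Condition}
#' @param nSamples number of retained samples (>= 1); default 50000
#' @param seed integer seed for this series
#' @param thin chain thinning stride (default 5)
#' @param burnFrac burn-in length as a fraction of `nSamples` (default 0.1)
#' @param xMax upper sampling bound, Angstrom; default `window d0 + 6`,
#'   never below `cmPos + 6`
#' @param biasConvention restraint convention, see [biasEnergy()]
#' @return a \linkS4class{ReactionCoordinateSeries}
#' @examples
#' m <- hexanePreset()$model
#' s <- sampleWindow(m, WindowSpec(6, 2), Condition(298, 0),
#'                   nSamples = 1000, seed = 1)
#' mean(xiValues(s))
#' @export
sampleWindow <- function(model, window, condition, nSamples = 50000L,
                         seed, thin = 5L, burnFrac = 0.1, xMax = NULL,
                         biasConvention = c("k_sq", "half_k_sq")) {
  stopifnot(is(model, "ModelPotential"), is(window, "WindowSpec"),
            is(condition, "Condition"))
  nSamples <- as.integer(nSamples)
  if (is.na(nSamples) || nSamples < 1L)
    stop("sampleWindow: 'nSamples' must be a positive integer")
  biasConvention <- match.arg(biasConvention)
  pref <- if (biasConvention == "k_sq") 1 else 0.5
  kbias <- pref * window@k

  p <- .modelParams(model, condition)
  kBT <- kB * condition@temperature
  if (is.null(xMax)) xMax <- max(window@d0 + 6, model@cmPos + 6)

  ## deterministic start: minimum of the biased potential on a fine grid
  grid <- seq(model@wallPos + 0.02, xMax, by = 0.01)
  etot <- .modelEval(p, grid) + kbias * (grid - window@d0)^2
  xiInit <- grid[which.min(etot)]
  ## step comparable to the target sd; the burn-in adaptation refines it
  stepInit <- max(0.05, min(0.5, sqrt(kBT / (2 * max(kbias, 0.5)))))
  nBurn <- max(500L, as.integer(ceiling(burnFrac * nSamples)))

  xi <- .withSeed(seed, .metropolisChain(p, window@d0, kbias, kBT,
                                         nSamples, as.integer(thin), nBurn,
                                         xiInit, stepInit, xMax))
  ReactionCoordinateSeries(window = window, condition = condition,
                           xi = xi, times = seq_along(xi) * 0.2,
                           seed = as.integer(seed))
}
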