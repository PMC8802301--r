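#' @describeIn WindowSpec-class compact display
#' @param object object to display
#' @export
setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec %s: d0 = %g A, k = %g kcal/mol/A^2\n",
              object@label, object@d0, object@k))
})

#' @describeIn Condition-class compact display
#' @param object object to display
#' @export
setMethod("show", "Condition", function(object) {
  cat(sprintf("Condition: T = %g K, IS = %g mol/dm^3\n",
              object@temperature, object@ionicStrength))
})

#' @describeIn ModelPotential-class compact display
#' @param object object to display
#' @export
setMethod("show", "ModelPotential", function(object) {
  q <- object@depthTQuad
  cat("ModelPotential (synthetic ground truth)\n")
  cat(sprintf("  CM at %g A; depth(T, IS) = %g + %g T + %g T^2 + %g IS\n",
              object@cmPos, q[1], q[2], q[3], object@depthISSlope))
  cat(sprintf("  depth(298 K, 0) = %.3f kcal/mol\n",
              cmDepth(object, 298, 0)))
  if (!is.na(object@dmPos))
    cat(sprintf("  DM at %g A (height %g); SSM at %g A (depth %g)\n",
                object@dmPos, object@dmHeight, object@ssmPos,
                object@ssmDepth))
  else cat("  no DM/SSM (contact minimum only)\n")
  cat(sprintf("  repulsive wall at %g A (scale %g)\n",
              object@wallPos, object@wallScale))
})

#' @describeIn ReactionCoordinateSeries-class compact display
#' @param object object to display
#' @export
setMethod("show", "ReactionCoordinateSeries", function(object) {
  cat(sprintf(
    "ReactionCoordinateSeries: %d samples, window %s, T = %g K, IS = %g\n",
    length(object@xi), object@window@label, object@condition@temperature,
    object@condition@ionicStrength))
  if (length(object@xi))
    cat(sprintf("  xi: mean %.3f A, sd %.3f A, range [%.3f, %.3f]\n",
                mean(object@xi), stats::sd(object@xi), min(object@xi),
                max(object@xi)))
})

setMethod("show", "StudyDataset", function(object) {
  nT <- length(unique(vapply(object@series, temperature, numeric(1))))
  nI <- length(unique(vapply(object@series, ionicStrength, numeric(1))))
  cat(sprintf(
    "StudyDataset: %d series (%d temperatures x %d ionic strengths), seed %d\n",
    length(object@series), nT, nI, object@seed))
})

setMethod("show", "HistogramSet", function(object) {
  cat(sprintf(
    "HistogramSet: %d windows, %d bins [%g, %g] A, T = %g K, IS = %g\n",
    length(object@windows), ncol(object@counts), min(object@binEdges),
    max(object@binEdges), object@condition@temperature,
    object@condition@ionicStrength))
  cat(sprintf("  retained %d, dropped %d samples\n",
              sum(object@nTotal), sum(object@dropped)))
})

setMethod("show", "PMFProfile", function(object) {
  def <- !is.na(object@F)
  cat(sprintf("PMFProfile: T = %g K, IS = %g; %d/%d bins defined\n",
              object@condition@temperature, object@condition@ionicStrength,
              sum(def), length(def)))
  cat(sprintf("  WHAM: %s after %d iterations; %d windows\n",
              if (isTRUE(object@converged)) "converged" else "NOT converged",
              object@iterations, length(object@windowShifts)))
  if (!anyNA(object@baselineRange))
    cat(sprintf("  baseline zeroed on [%g, %g] A\n",
                object@baselineRange[1], object@baselineRange[2]))
  if (any(def))
    cat(sprintf("  min F = %.3f kcal/mol at %.2f A\n",
                min(object@F[def]), object@binCenters[def][
                  which.min(object@F[def])]))
})

setMethod("show", "PMFFeatures", function(object) {
  cat(sprintf("PMFFeatures: CM at %.2f A, depth %.3f kcal/mol\n",
              object@cmPos, object@cmDepth))
  if (object@hasDM)
    cat(sprintf("  DM at %.2f A, height %.3f\n", object@dmPos,
                object@dmHeight))
  if (object@hasSSM)
    cat(sprintf("  SSM at %.2f A, depth %.3f\n", object@ssmPos,
                object@ssmDepth))
  if (!object@hasDM && !object@hasSSM)
    cat("  no DM/SSM (monotonic rise to baseline)\n")
})

setMethod("show", "ThermoFit", function(object) {
  cat(sprintf(
    "ThermoFit (IS = %g): dF(T) = %.4g %+.4g T %+.4g T^2 (%d points%s)\n",
    object@conditionIS, object@coef[1], object@coef[2], object@coef[3],
    object@nPoints, if (object@weighted) ", weighted" else ""))
})

setMethod("show", "ThermoState", function(object) {
  cat(sprintf("ThermoState at %g K:\n", object@temperature))
  cat(sprintf("  dF  = %8.4f +- %.4f kcal/mol\n", object@dF, object@dFerr))
  cat(sprintf("  dU  = %8.4f +- %.4f kcal/mol\n", object@dU, object@dUerr))
  cat(sprintf("  dS  = %8.5f +- %.5f kcal/mol/K\n", object@dS,
              object@dSerr))
  cat(sprintf("  dCv = %8.2f +- %.2f cal/mol/K\n", object@dCv,
              object@dCverr))
})

setMethod("show", "IonicFit", function(object) {
  cat(sprintf(
    "IonicFit (T = %g K): dF(IS) = %.4g %+.4g IS%s\n",
    object@conditionT, object@intercept, object@slope,
    if (object@saturated) " (saturated: covariance undefined)" else ""))
})

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport (seed %d, hydrotherm %s)\n", object@seed,
              object@version))
  cat(sprintf("  %d PMF profiles, %d feature rows\n",
              length(object@profiles), nrow(object@features)))
  cat(sprintf("  %d temperature fits, %d ionic fits\n",
              length(object@thermoFits), length(object@ionicFits)))
  bad <- object@status[!object@status$ok, , drop = FALSE]
  if (nrow(bad))
    cat(sprintf("  %d failed cell(s); see cellStatus()\n", nrow(bad)))
})
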