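#' Accessors
#'
#' Read-only access to the slots of the package's S4 objects.
#'
#' @name accessors
#' @return the requested component
NULL

#' @rdname accessors
#' @export
setMethod("temperature", "Condition", function(x) x@temperature)
#' @rdname accessors
#' @export
setMethod("ionicStrength", "Condition", function(x) x@ionicStrength)
#' @rdname accessors
#' @export
setMethod("temperature", "ReactionCoordinateSeries",
          function(x) x@condition@temperature)
#' @rdname accessors
#' @export
setMethod("ionicStrength", "ReactionCoordinateSeries",
          function(x) x@condition@ionicStrength)
#' @rdname accessors
#' @export
setMethod("temperature", "PMFProfile", function(x) x@condition@temperature)
#' @rdname accessors
#' @export
setMethod("ionicStrength", "PMFProfile", function(x) x@condition@ionicStrength)
#' @rdname accessors
#' @export
setMethod("temperature", "ThermoState", function(x) x@temperature)
#' @rdname accessors
#' @export
setMethod("ionicStrength", "ThermoFit", function(x) x@conditionIS)
#' @rdname accessors
#' @export
setMethod("temperature", "IonicFit", function(x) x@conditionT)

#' @rdname accessors
#' @export
setMethod("restraintCenter", "WindowSpec", function(x) x@d0)
#' @rdname accessors
#' @export
setMethod("forceConstant", "WindowSpec", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("restraintCenter", "ReactionCoordinateSeries",
          function(x) x@window@d0)
#' @rdname accessors
#' @export
setMethod("forceConstant", "ReactionCoordinateSeries", function(x) x@window@k)

#' @rdname accessors
#' @export
setMethod("xiValues", "ReactionCoordinateSeries", function(x) x@xi)
#' @rdname accessors
#' @export
setMethod("sampleTimes", "ReactionCoordinateSeries", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("length", "ReactionCoordinateSeries", function(x) length(x@xi))

#' @rdname accessors
#' @export
setMethod("seriesList", "StudyDataset", function(x) x@series)
#' @rdname accessors
#' @export
setMethod("groundTruth", "StudyDataset", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("length", "StudyDataset", function(x) length(x@series))

#' @rdname accessors
#' @export
setMethod("binEdges", "HistogramSet", function(x) x@binEdges)
#' @rdname accessors
#' @export
setMethod("binCounts", "HistogramSet", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("temperature", "HistogramSet", function(x) x@condition@temperature)

#' @rdname accessors
#' @export
setMethod("binCenters", "PMFProfile", function(x) x@binCenters)
#' @rdname accessors
#' @export
setMethod("pmfValues", "PMFProfile", function(x) x@F)
#' @rdname accessors
#' @export
setMethod("pmfErrors", "PMFProfile", function(x) x@Ferr)
#' @rdname accessors
#' @export
setMethod("binCounts", "PMFProfile", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("windowShifts", "PMFProfile", function(x) x@windowShifts)
#' @rdname accessors
#' @export
setMethod("isConverged", "PMFProfile", function(x) x@converged)
#' @rdname accessors
#' @export
setMethod("baselineRange", "PMFProfile", function(x) x@baselineRange)

#' @rdname accessors
#' @export
setMethod("cmPosition", "PMFFeatures", function(x) x@cmPos)
#' @rdname accessors
#' @export
setMethod("cmDepth", "PMFFeatures", function(x) x@cmDepth)
#' @rdname accessors
#' @export
setMethod("dmPosition", "PMFFeatures", function(x) x@dmPos)
#' @rdname accessors
#' @export
setMethod("dmHeight", "PMFFeatures", function(x) x@dmHeight)
#' @rdname accessors
#' @export
setMethod("ssmPosition", "PMFFeatures", function(x) x@ssmPos)
#' @rdname accessors
#' @export
setMethod("ssmDepth", "PMFFeatures", function(x) x@ssmDepth)
#' @rdname accessors
#' @export
setMethod("hasDM", "PMFFeatures", function(x) x@hasDM)
#' @rdname accessors
#' @export
setMethod("hasSSM", "PMFFeatures", function(x) x@hasSSM)

#' @rdname accessors
#' @param object a `ThermoFit` or `IonicFit`
#' @export
setMethod("coef", "ThermoFit", function(object) object@coef)
#' @rdname accessors
#' @export
setMethod("vcov", "ThermoFit", function(object) object@cov)
#' @rdname accessors
#' @export
setMethod("coef", "IonicFit",
          function(object) c(intercept = object@intercept,
                             slope = object@slope))
#' @rdname accessors
#' @export
setMethod("vcov", "IonicFit", function(object) object@cov)

#' @rdname accessors
#' @export
setMethod("profiles", "StudyReport", function(x) x@profiles)
#' @rdname accessors
#' @export
setMethod("featureTable", "StudyReport", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("thermoFits", "StudyReport", function(x) x@thermoFits)
#' @rdname accessors
#' @export
setMethod("thermoStates", "StudyReport", function(x) x@thermoStates)
#' @rdname accessors
#' @export
setMethod("ionicFits", "StudyReport", function(x) x@ionicFits)
#' @rdname accessors
#' @export
setMethod("cellStatus", "StudyReport", function(x) x@status)
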