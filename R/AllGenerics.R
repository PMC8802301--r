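## Accessor generics. Slot access from user code is discouraged; these are
## the supported surface.

#' @rdname accessors
#' @param x an object from this package
#' @param ... passed to methods
#' @export
setGeneric("temperature", function(x, ...) standardGeneric("temperature"))

#' @rdname accessors
#' @export
setGeneric("ionicStrength", function(x, ...) standardGeneric("ionicStrength"))

#' @rdname accessors
#' @export
setGeneric("restraintCenter",
           function(x, ...) standardGeneric("restraintCenter"))

#' @rdname accessors
#' @export
setGeneric("forceConstant", function(x, ...) standardGeneric("forceConstant"))

#' @rdname accessors
#' @export
setGeneric("xiValues", function(x, ...) standardGeneric("xiValues"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x, ...) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("seriesList", function(x, ...) standardGeneric("seriesList"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("binCenters", function(x, ...) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(x, ...) standardGeneric("binEdges"))

#' @rdname accessors
#' @export
setGeneric("binCounts", function(x, ...) standardGeneric("binCounts"))

#' @rdname accessors
#' @export
setGeneric("pmfValues", function(x, ...) standardGeneric("pmfValues"))

#' @rdname accessors
#' @export
setGeneric("pmfErrors", function(x, ...) standardGeneric("pmfErrors"))

#' @rdname accessors
#' @export
setGeneric("windowShifts", function(x, ...) standardGeneric("windowShifts"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x, ...) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("baselineRange", function(x, ...) standardGeneric("baselineRange"))

#' Ground-truth contact-minimum depth at a condition
#'
#' For a \linkS4class{ModelPotential}, the configured depth law
#' `a + b*T + c*T^2 + depthISSlope * IS`; for \linkS4class{PMFFeatures},
#' the located depth.
#'
#' @param x a `ModelPotential` or `PMFFeatures`
#' @param ... `temperature` and `ionicStrength` for the model method
#' @export
setGeneric("cmDepth", function(x, ...) standardGeneric("cmDepth"))

#' @rdname accessors
#' @export
setGeneric("cmPosition", function(x, ...) standardGeneric("cmPosition"))

#' @rdname accessors
#' @export
setGeneric("dmPosition", function(x, ...) standardGeneric("dmPosition"))

#' @rdname accessors
#' @export
setGeneric("dmHeight", function(x, ...) standardGeneric("dmHeight"))

#' @rdname accessors
#' @export
setGeneric("ssmPosition", function(x, ...) standardGeneric("ssmPosition"))

#' @rdname accessors
#' @export
setGeneric("ssmDepth", function(x, ...) standardGeneric("ssmDepth"))

#' @rdname accessors
#' @export
setGeneric("hasDM", function(x, ...) standardGeneric("hasDM"))

#' @rdname accessors
#' @export
setGeneric("hasSSM", function(x, ...) standardGeneric("hasSSM"))

#' @rdname accessors
#' @export
setGeneric("featureTable", function(x, ...) standardGeneric("featureTable"))

#' @rdname accessors
#' @export
setGeneric("profiles", function(x, ...) standardGeneric("profiles"))

#' @rdname accessors
#' @export
setGeneric("thermoFits", function(x, ...) standardGeneric("thermoFits"))

#' @rdname accessors
#' @export
setGeneric("thermoStates", function(x, ...) standardGeneric("thermoStates"))

#' @rdname accessors
#' @export
setGeneric("ionicFits", function(x, ...) standardGeneric("ionicFits"))

#' @rdname accessors
#' @export
setGeneric("cellStatus", function(x, ...) standardGeneric("cellStatus"))
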