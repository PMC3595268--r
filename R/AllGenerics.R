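#' @include AllClasses.R
NULL

#' Accessors for FRAP containers
#'
#' Small accessor generics for the S4 containers: acquisition times,
#' region traces, pre-bleach frame count, paired ground truth, normalized
#' values and the F_pre/F_post/F_end summary intensities.
#'
#' @param object a \linkS4class{FrapSeries}, \linkS4class{NormalizedCurve}
#'   or \linkS4class{FrapEstimate}.
#' @return the corresponding slot value.
#' @name frap-accessors
NULL

#' @rdname frap-accessors
#' @export
setGeneric("frapTimes", function(object) standardGeneric("frapTimes"))
#' @rdname frap-accessors
#' @export
setGeneric("roiMean", function(object) standardGeneric("roiMean"))
#' @rdname frap-accessors
#' @export
setGeneric("totalMean", function(object) standardGeneric("totalMean"))
#' @rdname frap-accessors
#' @export
setGeneric("backgroundMean", function(object) standardGeneric("backgroundMean"))
#' @rdname frap-accessors
#' @export
setGeneric("nPre", function(object) standardGeneric("nPre"))
#' @rdname frap-accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname frap-accessors
#' @export
setGeneric("curveValues", function(object) standardGeneric("curveValues"))
#' @rdname frap-accessors
#' @export
setGeneric("fPre", function(object) standardGeneric("fPre"))
#' @rdname frap-accessors
#' @export
setGeneric("fPost", function(object) standardGeneric("fPost"))
#' @rdname frap-accessors
#' @export
setGeneric("fEnd", function(object) standardGeneric("fEnd"))
#' @rdname frap-accessors
#' @export
setGeneric("endWindow", function(object) standardGeneric("endWindow"))
#' @rdname frap-accessors
#' @export
setGeneric("halfTimeS", function(object) standardGeneric("halfTimeS"))
#' @rdname frap-accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname frap-accessors
#' @export
setGeneric("fitRMSE", function(object) standardGeneric("fitRMSE"))

#' @rdname subtractBackground
#' @export
setGeneric("subtractBackground",
           function(series, ...) standardGeneric("subtractBackground"))

#' @rdname acquisitionCorrection
#' @export
setGeneric("acquisitionCorrection",
           function(series, ...) standardGeneric("acquisitionCorrection"))

#' @rdname normalizeFrap
#' @export
setGeneric("normalizeFrap",
           function(series, ...) standardGeneric("normalizeFrap"))

#' @rdname mobileFraction
#' @export
setGeneric("mobileFraction",
           function(object, ...) standardGeneric("mobileFraction"))

#' @rdname halfTime
#' @export
setGeneric("halfTime", function(object, ...) standardGeneric("halfTime"))

#' @rdname analyzeFrap
#' @export
setGeneric("analyzeFrap", function(series, ...) standardGeneric("analyzeFrap"))

#' @rdname generateFrapSeries
#' @export
setGeneric("generateFrapSeries",
           function(truth, ...) standardGeneric("generateFrapSeries"))

#' @rdname generateNucleiImage
#' @export
setGeneric("generateNucleiImage",
           function(truth, ...) standardGeneric("generateNucleiImage"))
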