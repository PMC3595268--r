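#' @include AllGenerics.R
NULL

#' @rdname frap-accessors
setMethod("frapTimes", "FrapSeries", function(object) object@timeS)
#' @rdname frap-accessors
setMethod("frapTimes", "NormalizedCurve", function(object) object@timeS)
#' @rdname frap-accessors
setMethod("roiMean", "FrapSeries", function(object) object@roiMean)
#' @rdname frap-accessors
setMethod("totalMean", "FrapSeries", function(object) object@totalMean)
#' @rdname frap-accessors
setMethod("backgroundMean", "FrapSeries", function(object) object@backgroundMean)
#' @rdname frap-accessors
setMethod("nPre", "FrapSeries", function(object) object@nPre)
#' @rdname frap-accessors
setMethod("nPre", "NormalizedCurve", function(object) object@nPre)
#' @rdname frap-accessors
setMethod("groundTruth", "FrapSeries", function(object) object@truth)
#' @rdname frap-accessors
setMethod("curveValues", "NormalizedCurve", function(object) object@value)
#' @rdname frap-accessors
setMethod("fPre", "NormalizedCurve", function(object) object@fPre)
#' @rdname frap-accessors
setMethod("fPost", "NormalizedCurve", function(object) object@fPost)
#' @rdname frap-accessors
setMethod("fEnd", "NormalizedCurve", function(object) object@fEnd)
#' @rdname frap-accessors
setMethod("endWindow", "NormalizedCurve", function(object) object@endWindow)
#' @rdname frap-accessors
setMethod("fPre", "FrapEstimate", function(object) object@fPre)
#' @rdname frap-accessors
setMethod("fPost", "FrapEstimate", function(object) object@fPost)
#' @rdname frap-accessors
setMethod("fEnd", "FrapEstimate", function(object) object@fEnd)
#' @rdname frap-accessors
setMethod("endWindow", "FrapEstimate", function(object) object@endWindow)
#' @rdname frap-accessors
setMethod("halfTimeS", "FrapEstimate", function(object) object@halfTimeS)
#' @rdname frap-accessors
setMethod("converged", "FrapEstimate", function(object) object@converged)
#' @rdname frap-accessors
setMethod("fitRMSE", "FrapEstimate", function(object) object@fitRMSE)

#' @describeIn mobileFraction accessor: the stored mobile fraction of an
#'   estimate.
#' @export
setMethod("mobileFraction", "FrapEstimate",
          function(object, ...) object@mobileFraction)

setMethod("show", "FrapGroundTruth", function(object) {
    cat("FrapGroundTruth: M_f =", object@mobileFraction,
        ", T_1/2 =", object@halfTime, "s, depth =", object@postBleachDepth,
        "\n  lambda =", object@monitorBleachRate, "/s, noise SD =",
        object@noiseSd, ", background =", object@backgroundLevel,
        "\n  frames:", object@nPre, "pre +", object@nPost, "post @",
        object@frameInterval, "s, seed =", object@seed, "\n")
})

setMethod("show", "ImageGroundTruth", function(object) {
    cat("ImageGroundTruth:", object@nCells, "nuclei (r =",
        object@nucleusRadius, "px),", object@nucleoliPerCell,
        "nucleoli/cell (r =", object@nucleolusRadius, "px)\n",
        " target ratio =", object@trueRatio, ", blur =", object@blurSigma,
        "px, noise SD =", object@noiseSd, ", shape =",
        paste(object@imageShape, collapse = " x "),
        ", seed =", object@seed, "\n")
})

setMethod("show", "FrapSeries", function(object) {
    cat("FrapSeries:", length(object@timeS), "frames (",
        object@nPre, "pre-bleach ), t =", min(object@timeS), "..",
        max(object@timeS), "s\n  roi mean range:",
        signif(min(object@roiMean), 4), "..", signif(max(object@roiMean), 4),
        if (!is.null(object@truth)) "\n  paired ground truth attached" else "",
        "\n")
})

setMethod("show", "NormalizedCurve", function(object) {
    cat("NormalizedCurve:", length(object@value) - object@nPre,
        "post-bleach frames; F_post =", signif(object@fPost, 4),
        ", F_end =", signif(object@fEnd, 4),
        "( window =", object@endWindow, ")\n")
})

setMethod("show", "FrapEstimate", function(object) {
    cat("FrapEstimate: M_f =", signif(object@mobileFraction, 4),
        ", T_1/2 =", signif(object@halfTimeS, 4), "s [", object@method,
        if (!object@converged) ", NOT converged" else "", "]\n")
})

setMethod("show", "LabeledMasks", function(object) {
    cat("LabeledMasks:", max(0L, max(object@nuclearLabels)), "nuclei,",
        sum(object@nucleolarMask), "nucleolar px over",
        paste(dim(object@nuclearLabels), collapse = " x "), "image\n")
})

#' Flatten a FrapEstimate into a one-row data.frame
#'
#' Column layout matches the per-cell estimates CSV written by
#' [writeMeasurements()]: \code{mobile_fraction}, \code{half_time_s},
#' \code{method}, \code{f_pre}, \code{f_post}, \code{f_end},
#' \code{end_window}, \code{fit_rmse}, \code{converged}.
#'
#' @param x a \linkS4class{FrapEstimate}.
#' @param row.names,optional,... ignored, present for generic compatibility.
#' @return one-row data.frame.
#' @export
as.data.frame.FrapEstimate <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
    data.frame(mobile_fraction = x@mobileFraction,
               half_time_s = x@halfTimeS,
               method = x@method,
               f_pre = x@fPre, f_post = x@fPost, f_end = x@fEnd,
               end_window = x@endWindow,
               fit_rmse = x@fitRMSE, converged = x@converged,
               stringsAsFactors = FALSE)
}
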