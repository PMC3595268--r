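#' @include AllGenerics.R
NULL

#' Subtract the background trace from a FRAP series
#'
#' Frame-wise subtraction of the background-region trace from both the
#' bleached-region and whole-nucleus traces; the background trace is set
#' to zero afterwards. Results that would go negative are clipped at 0
#' with a warning (this indicates the background region was brighter than
#' the signal region and should be inspected).
#'
#' @param series a \linkS4class{FrapSeries}.
#' @param ... unused.
#' @return the background-subtracted \linkS4class{FrapSeries}.
#' @export
setMethod("subtractBackground", "FrapSeries", function(series, ...) {
    validObject(series)
    roi <- series@roiMean - series@backgroundMean
    tot <- series@totalMean - series@backgroundMean
    nNeg <- sum(roi < 0) + sum(tot < 0)
    if (nNeg > 0L) {
        warning(nNeg, " frame value(s) fell below 0 after background ",
                "subtraction and were clipped")
        roi <- pmax(roi, 0)
        tot <- pmax(tot, 0)
    }
    initialize(series, roiMean = roi, totalMean = tot,
               backgroundMean = rep(0, length(series@backgroundMean)))
})

#' Correct a FRAP series for acquisition (monitor) photobleaching
#'
#' Repeated imaging gradually bleaches the whole cell; the whole-nucleus
#' trace records that decay. The bleached-region trace is rescaled
#' frame-wise by the ratio of the pre-bleach mean of the whole-nucleus
#' trace to its current value,
#' \deqn{roi'(t) = roi(t) \cdot \bar{T}_{pre} / T(t),}
#' which exactly cancels any multiplicative decay shared by the two
#' traces. Requires background-subtracted input with a strictly positive
#' whole-nucleus trace.
#'
#' @param series a background-subtracted \linkS4class{FrapSeries}.
#' @param ... unused.
#' @return the corrected \linkS4class{FrapSeries}.
#' @export
setMethod("acquisitionCorrection", "FrapSeries", function(series, ...) {
    validObject(series)
    bad <- which(series@totalMean <= 0)
    if (length(bad))
        stop("acquisition correction impossible: whole-nucleus trace is ",
             "<= 0 at frame(s) ", paste(utils::head(bad, 5L), collapse = ", "))
    tPre <- mean(series@totalMean[seq_len(series@nPre)])
    initialize(series, roiMean = series@roiMean * tPre / series@totalMean)
})

#' Normalize a corrected FRAP series to its pre-bleach level
#'
#' Divides the bleached-region trace by F_pre, the mean of the
#' \code{nPre} pre-bleach frames, and re-zeroes time at the first
#' post-bleach frame. F_post is the value of the first post-bleach frame
#' (no averaging); F_end is the mean of the terminal plateau window of
#' \code{min(20, floor(nPost/4))} frames, never fewer than 3 (and never
#' more than the number of post-bleach frames).
#'
#' With \code{perFrameTotal = TRUE} the classic full double normalization
#' is used instead: each frame's ratio roi(t)/total(t) is normalized by
#' the pre-bleach mean of that ratio. After [acquisitionCorrection()] the
#' two forms coincide up to second order in the per-frame decay, so the
#' default leaves this off.
#'
#' @param series a background-subtracted, corrected
#'   \linkS4class{FrapSeries}.
#' @param endWindow \code{"auto"} for the rule above, or an explicit
#'   number of terminal frames.
#' @param perFrameTotal use the per-frame roi/total double normalization.
#' @param ... unused.
#' @return a \linkS4class{NormalizedCurve}.
#' @export
setMethod("normalizeFrap", "FrapSeries",
          function(series, endWindow = "auto", perFrameTotal = FALSE, ...) {
    validObject(series)
    nPre  <- series@nPre
    nPost <- length(series@timeS) - nPre
    vals <- if (perFrameTotal) {
        if (any(series@totalMean <= 0))
            stop("per-frame normalization impossible: whole-nucleus trace ",
                 "is <= 0")
        series@roiMean / series@totalMean
    } else series@roiMean
    fPreRaw <- mean(vals[seq_len(nPre)])
    if (fPreRaw <= 0)
        stop("normalization impossible: pre-bleach mean F_pre <= 0")
    value <- vals / fPreRaw
    ew <- if (identical(endWindow, "auto")) {
        min(max(3L, min(20L, nPost %/% 4L)), nPost)
    } else {
        ew <- as.integer(endWindow)
        if (ew < 1L || ew > nPost)
            stop("endWindow must be between 1 and the number of post-bleach frames")
        ew
    }
    new("NormalizedCurve",
        timeS = series@timeS - series@timeS[nPre + 1L],
        value = value, nPre = nPre, fPre = 1,
        fPost = value[nPre + 1L],
        fEnd = mean(value[(length(value) - ew + 1L):length(value)]),
        endWindow = ew, preLevel = fPreRaw)
})

#' Mobile fraction of a normalized recovery curve
#'
#' \deqn{M_f = (F_{end} - F_{post}) / (F_{pre} - F_{post})}
#' The fraction of fluorophores free to exchange with the bleached region:
#' 1 means the plateau returns to the pre-bleach level, 0 means no
#' recovery. The value is reported as computed (not clipped); noise can
#' push it slightly above 1, and values above 1.05 raise a warning flag.
#'
#' @param object a \linkS4class{NormalizedCurve} (or a
#'   \linkS4class{FrapEstimate}, for which the stored value is returned).
#' @param ... unused.
#' @return the mobile fraction, dimensionless.
#' @export
setMethod("mobileFraction", "NormalizedCurve", function(object, ...) {
    validObject(object)
    if (object@fPre <= object@fPost)
        stop("mobile fraction undefined: F_pre <= F_post (no bleach detected)")
    mf <- (object@fEnd - object@fPost) / (object@fPre - object@fPost)
    if (mf > 1.05)
        warning("mobile fraction ", signif(mf, 4),
                " exceeds 1.05; check background and correction")
    mf
})

## first crossing of the half-recovery level by linear interpolation
interpolateHalfTime <- function(t, v, fPost, fEnd) {
    target <- fPost + (fEnd - fPost) / 2
    above <- which(v >= target)
    above <- above[above > 1L]
    if (!length(above)) return(NA_real_)
    i <- above[1L]
    dv <- v[i] - v[i - 1L]
    if (dv == 0) return(t[i - 1L])  # flat crossing (no-recovery curve)
    t[i - 1L] + (target - v[i - 1L]) / dv * (t[i] - t[i - 1L])
}

#' Recovery half-time of a normalized curve
#'
#' Two estimators of T_1/2, the time for the bleached region to recover
#' half of its plateau recovery:
#' \describe{
#'   \item{exp_fit (default)}{least-squares fit of
#'     \eqn{v(t) = F'_{end} - (F'_{end} - F_{post})\,e^{-t \ln 2 / h}}
#'     over the post-bleach frames, with \eqn{F'_{end}} and \eqn{h} free
#'     and \eqn{F_{post}} fixed at the observed first post-bleach value;
#'     T_1/2 = h.}
#'   \item{interpolation}{the smallest time where the linearly
#'     interpolated curve crosses \eqn{F_{post} + (F_{end}-F_{post})/2};
#'     model-free cross-check.}
#' }
#' If the exponential fit fails to converge, the interpolation value is
#' returned with \code{converged = FALSE} and a message.
#'
#' @param object a \linkS4class{NormalizedCurve}.
#' @param method \code{"exp_fit"} or \code{"interpolation"}.
#' @param ... unused.
#' @return a \linkS4class{FrapEstimate} (mobile fraction included).
#' @export
setMethod("halfTime", "NormalizedCurve",
          function(object, method = c("exp_fit", "interpolation"), ...) {
    validObject(object)
    method <- match.arg(method)
    mf <- mobileFraction(object)
    post <- (object@nPre + 1L):length(object@value)
    t <- object@timeS[post]
    v <- object@value[post]
    fPost <- object@fPost
    hInterp <- interpolateHalfTime(t, v, fPost, object@fEnd)
    mk <- function(h, method, rmse, conv)
        new("FrapEstimate", mobileFraction = mf, halfTimeS = h,
            method = method, fitRMSE = rmse, converged = conv,
            fPre = object@fPre, fPost = fPost, fEnd = object@fEnd,
            endWindow = object@endWindow)
    if (method == "interpolation")
        return(mk(hInterp, "interpolation", 0, !is.na(hInterp)))
    h0 <- if (is.finite(hInterp) && hInterp > 0) hInterp
          else max(diff(t)[1L], diff(range(t)) / 10)
    fit <- tryCatch(
        minpack.lm::nlsLM(v ~ fend - (fend - fPost) * exp(-t * log(2) / h),
                          start = list(fend = object@fEnd, h = h0),
                          lower = c(fend = -Inf, h = 1e-9),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    if (is.null(fit)) {
        message("exponential half-time fit did not converge; ",
                "falling back to interpolation")
        return(mk(hInterp, "exp_fit", NA_real_, FALSE))
    }
    co <- stats::coef(fit)
    mk(unname(co["h"]), "exp_fit",
       sqrt(mean(stats::residuals(fit)^2)), TRUE)
})

#' Analyze a raw FRAP series end to end
#'
#' Runs the full quantification in acquisition order: background
#' subtraction, acquisition (monitor) bleaching correction, pre-bleach
#' normalization, then mobile fraction and recovery half-time.
#'
#' @param series a raw \linkS4class{FrapSeries}.
#' @param method half-time estimator, \code{"exp_fit"} or
#'   \code{"interpolation"}.
#' @param endWindow terminal plateau window, \code{"auto"} or a count.
#' @param doubleNormalization if TRUE, skip the separate correction step
#'   and use the per-frame roi/total double normalization instead
#'   (equivalent up to second order in the per-frame decay).
#' @param ... unused.
#' @return a \linkS4class{FrapEstimate}.
#' @examples
#' truth <- FrapGroundTruth(seed = 1, mobileFraction = 0.89, halfTime = 4.3)
#' analyzeFrap(generateFrapSeries(truth))
#' @export
setMethod("analyzeFrap", "FrapSeries",
          function(series, method = c("exp_fit", "interpolation"),
                   endWindow = "auto", doubleNormalization = FALSE, ...) {
    method <- match.arg(method)
    s <- subtractBackground(series)
    curve <- if (doubleNormalization) {
        normalizeFrap(s, endWindow = endWindow, perFrameTotal = TRUE)
    } else {
        normalizeFrap(acquisitionCorrection(s), endWindow = endWindow)
    }
    halfTime(curve, method = method)
})

#' Analyze a set of FRAP series into a per-cell table
#'
#' Convenience wrapper applying [analyzeFrap()] to a list of series and
#' binding the per-cell estimates into the standard measurements table.
#'
#' @param seriesList list of \linkS4class{FrapSeries}, optionally named by
#'   cell id.
#' @param ... passed to [analyzeFrap()].
#' @return a data.frame with one row per cell: cell_id, mobile_fraction,
#'   half_time_s, method, f_pre, f_post, f_end, end_window, fit_rmse,
#'   converged.
#' @export
analyzeFrapSet <- function(seriesList, ...) {
    ids <- names(seriesList)
    if (is.null(ids)) ids <- sprintf("cell%03d", seq_along(seriesList))
    rows <- lapply(seq_along(seriesList), function(i) {
        est <- analyzeFrap(seriesList[[i]], ...)
        cbind(data.frame(cell_id = ids[i], stringsAsFactors = FALSE),
              as.data.frame(est))
    })
    do.call(rbind, rows)
}

#' Long-format normalized curve for plotting
#'
#' @param curve a \linkS4class{NormalizedCurve}.
#' @param cellId identifier copied into the table.
#' @return data.frame(cell_id, time_s, value).
#' @export
curveTable <- function(curve, cellId = "cell001") {
    data.frame(cell_id = cellId, time_s = curve@timeS, value = curve@value,
               stringsAsFactors = FALSE)
}
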