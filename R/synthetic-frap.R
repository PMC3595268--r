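#' @include AllGenerics.R
NULL

## ideal (noise-free, decay-free, background-free) traces for a ground truth;
## shared by the series and stack generators and by tests
idealFrapTraces <- function(truth) {
    n  <- truth@nPre + truth@nPost
    dt <- truth@frameInterval
    tTotal <- (seq_len(n) - 1L) * dt
    tPost  <- (seq_len(truth@nPost) - 1L) * dt  # 0 at first post-bleach frame
    P <- truth@preBleachLevel
    d <- truth@postBleachDepth
    m <- truth@mobileFraction
    h <- truth@halfTime
    roi <- c(rep(P, truth@nPre),
             P * (d + m * (1 - d) * (1 - 2^(-tPost / h))))
    ## energy accounting: the bleach destroys a fraction
    ## bleachSpotFraction * (1 - d) of the total nuclear signal, permanently
    total <- c(rep(P, truth@nPre),
               rep(P * (1 - truth@bleachSpotFraction * (1 - d)), truth@nPost))
    list(tTotal = tTotal, roi = roi, total = total)
}

#' Simulate a FRAP acquisition as region-mean traces
#'
#' Generates the three per-frame region traces of a FRAP experiment
#' (bleached region, whole nucleus, background) from a
#' \linkS4class{FrapGroundTruth}. Pre-bleach frames sit at the pre-bleach
#' level P; post-bleach frames follow the single-exponential recovery with
#' an immobile fraction,
#' \deqn{R(t) = P\,[d + m(1-d)(1 - 2^{-t/h})], \quad t \ge 0,}
#' with the first post-bleach frame at t = 0. The bleached-region and
#' whole-nucleus traces are multiplied by the monitor decay
#' \eqn{e^{-\lambda t}} counted from the first acquired frame, the
#' whole-nucleus trace drops at the bleach by the signal destroyed in the
#' bleach spot (lost, not redistributed), the background level is added to
#' all three traces, and independent Gaussian noise of \code{noiseSd} is
#' added per frame. Identical seeds give bit-identical output.
#'
#' @param truth a \linkS4class{FrapGroundTruth}.
#' @param ... unused.
#' @return a \linkS4class{FrapSeries} with the ground truth attached.
#' @examples
#' s <- generateFrapSeries(FrapGroundTruth(seed = 1))
#' analyzeFrap(s)
#' @export
setMethod("generateFrapSeries", "FrapGroundTruth", function(truth, ...) {
    validObject(truth)
    ideal <- idealFrapTraces(truth)
    decay <- exp(-truth@monitorBleachRate * ideal$tTotal)
    roi   <- ideal$roi * decay
    total <- ideal$total * decay
    bg    <- rep(truth@backgroundLevel, length(ideal$tTotal))
    if (truth@noiseSd > 0) {
        n <- length(ideal$tTotal)
        noise <- withr::with_seed(truth@seed,
                                  stats::rnorm(3L * n, sd = truth@noiseSd))
        roi   <- roi   + noise[seq_len(n)]
        total <- total + noise[n + seq_len(n)]
        bg    <- bg    + noise[2L * n + seq_len(n)]
    }
    FrapSeries(timeS = ideal$tTotal,
               roiMean = roi + truth@backgroundLevel,
               totalMean = total + truth@backgroundLevel,
               backgroundMean = bg,
               nPre = truth@nPre, truth = truth)
})

## ---- image-stack variant ----------------------------------------------------

rasterDisk <- function(shape, center, radius) {
    ## pixel (i, j) is inside if its center lies within the circle;
    ## 0-based pixel index k has center at k, matching the ground-truth
    ## convention of integer pixel coordinates. Only the bounding box is
    ## evaluated.
    mask <- matrix(FALSE, shape[1L], shape[2L])
    ri <- max(1L, floor(center[1L] - radius) + 1L):
          min(shape[1L], ceiling(center[1L] + radius) + 1L)
    rj <- max(1L, floor(center[2L] - radius) + 1L):
          min(shape[2L], ceiling(center[2L] + radius) + 1L)
    di <- (ri - 1L) - center[1L]
    dj <- (rj - 1L) - center[2L]
    mask[ri, rj] <- outer(di^2, dj^2, `+`) <= radius^2
    mask
}

#' Region layout for a simulated FRAP image stack
#'
#' Defines the geometry painted by [generateFrapStack()]: a circular
#' nucleus, a circular bleach region fully inside it, and a circular
#' background region disjoint from the nucleus. Centers are 0-based
#' (row, col) pixel coordinates.
#'
#' @param imageShape c(rows, cols) of each frame.
#' @param nucleusCenter,nucleusRadius nucleus disk.
#' @param bleachCenter,bleachRadius bleach disk (must lie inside the
#'   nucleus).
#' @param backgroundCenter,backgroundRadius background disk (must not
#'   intersect the nucleus).
#' @return a list with the three logical masks, a combined integer label
#'   matrix (1 = bleach, 2 = rest of nucleus, 3 = background region) and
#'   the geometry parameters.
#' @export
frapRegionLayout <- function(imageShape = c(128L, 128L),
                             nucleusCenter = c(70, 70), nucleusRadius = 42,
                             bleachCenter = c(60, 60), bleachRadius = 8,
                             backgroundCenter = c(12, 115),
                             backgroundRadius = 9) {
    imageShape <- as.integer(imageShape)
    if (sqrt(sum((bleachCenter - nucleusCenter)^2)) + bleachRadius >
            nucleusRadius)
        stop("bleach region must lie entirely inside the nucleus")
    if (sqrt(sum((backgroundCenter - nucleusCenter)^2)) <
            nucleusRadius + backgroundRadius)
        stop("background region must not overlap the nucleus")
    inBounds <- function(c., r)
        all(c. - r >= 0) && c.[1L] + r <= imageShape[1L] - 1L &&
            c.[2L] + r <= imageShape[2L] - 1L
    if (!inBounds(nucleusCenter, nucleusRadius) ||
            !inBounds(backgroundCenter, backgroundRadius))
        stop("regions out of image bounds")
    nucleus <- rasterDisk(imageShape, nucleusCenter, nucleusRadius)
    bleach  <- rasterDisk(imageShape, bleachCenter, bleachRadius)
    backgr  <- rasterDisk(imageShape, backgroundCenter, backgroundRadius)
    labels  <- matrix(0L, imageShape[1L], imageShape[2L])
    labels[nucleus] <- 2L
    labels[bleach]  <- 1L
    labels[backgr]  <- 3L
    list(imageShape = imageShape, nucleus = nucleus, bleach = bleach,
         background = backgr, labels = labels,
         nucleusCenter = nucleusCenter, nucleusRadius = nucleusRadius,
         bleachCenter = bleachCenter, bleachRadius = bleachRadius,
         backgroundCenter = backgroundCenter,
         backgroundRadius = backgroundRadius)
}

#' Simulate a FRAP acquisition as an image stack
#'
#' Image-level variant of [generateFrapSeries()]: renders each frame so
#' that the mean over the bleach region equals the bleached-region trace,
#' the mean over the whole nucleus equals the whole-nucleus trace, and
#' pixels outside the nucleus carry the background trace. Region means are
#' painted uniformly (frame noise from the ground truth enters through the
#' traces), so extraction with [extractFrapSeries()] returns the
#' [generateFrapSeries()] output exactly in float mode and within the
#' rounding bound (±0.5 intensity units) in 16-bit mode.
#'
#' @param truth a \linkS4class{FrapGroundTruth}.
#' @param layout a region layout from [frapRegionLayout()].
#' @param bitDepth \code{"float"} (exact) or \code{"16bit"} (values rounded
#'   to integers and clipped to [0, 65535]).
#' @return a list: \code{stack} (rows x cols x frames array), \code{layout},
#'   \code{series} (the underlying \linkS4class{FrapSeries}) and
#'   \code{truth}.
#' @export
generateFrapStack <- function(truth, layout = frapRegionLayout(),
                              bitDepth = c("16bit", "float")) {
    bitDepth <- match.arg(bitDepth)
    series <- generateFrapSeries(truth)
    nFrames <- length(series@timeS)
    shape <- layout$imageShape
    nNuc    <- sum(layout$nucleus)
    nBleach <- sum(layout$bleach)
    restIdx <- which(layout$nucleus & !layout$bleach)
    outIdx  <- which(!layout$nucleus)
    bleachIdx <- which(layout$bleach)
    stack <- array(0, dim = c(shape[1L], shape[2L], nFrames))
    for (f in seq_len(nFrames)) {
        frame <- matrix(0, shape[1L], shape[2L])
        roi <- series@roiMean[f]
        tot <- series@totalMean[f]
        ## rest-of-nucleus value chosen so the whole-nucleus mean is exact
        rest <- (tot * nNuc - roi * nBleach) / (nNuc - nBleach)
        frame[bleachIdx] <- roi
        frame[restIdx]  <- rest
        frame[outIdx]   <- series@backgroundMean[f]
        stack[, , f] <- frame
    }
    if (bitDepth == "16bit")
        stack <- pmin(pmax(round(stack), 0), 65535)
    list(stack = stack, layout = layout, series = series, truth = truth)
}

#' Extract region-mean FRAP traces from an image stack
#'
#' Reader path from pixels: computes per-frame means of the bleach region,
#' the whole nucleus (bleach region included) and the background region
#' defined by a [frapRegionLayout()], returning a \linkS4class{FrapSeries}.
#'
#' @param stack rows x cols x frames numeric array.
#' @param layout region layout matching the stack dimensions.
#' @param nPre number of pre-bleach frames.
#' @param frameInterval seconds between frames (time base of the result).
#' @return a \linkS4class{FrapSeries}.
#' @export
extractFrapSeries <- function(stack, layout, nPre = 3L, frameInterval = 1) {
    if (!identical(dim(stack)[1:2], as.integer(layout$imageShape)))
        stop("stack dimensions do not match the region layout")
    nFrames <- dim(stack)[3L]
    nucIdx <- which(layout$nucleus)
    blIdx  <- which(layout$bleach)
    bgIdx  <- which(layout$background)
    perFrame <- function(idx) vapply(seq_len(nFrames), function(f) {
        mean(stack[, , f][idx])
    }, numeric(1L))
    FrapSeries(timeS = (seq_len(nFrames) - 1L) * frameInterval,
               roiMean = perFrame(blIdx),
               totalMean = perFrame(nucIdx),
               backgroundMean = perFrame(bgIdx),
               nPre = nPre)
}
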