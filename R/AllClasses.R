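#' @import methods
NULL

## ---- ground truth for the FRAP simulator -----------------------------------

#' Ground truth for a simulated FRAP experiment
#'
#' Parameter record describing one simulated fluorescence-recovery-after-
#' photobleaching (FRAP) acquisition. The simulated bleached-region trace
#' follows, for post-bleach time \eqn{t \ge 0},
#' \deqn{R(t) = P\,[d + m(1-d)(1 - 2^{-t/h})]}
#' where \eqn{P} is the pre-bleach level, \eqn{d} the post-bleach depth,
#' \eqn{m} the mobile fraction and \eqn{h} the recovery half-time.
#' Both the bleached-region and whole-nucleus traces additionally decay as
#' \eqn{e^{-\lambda t}} from the first acquired frame (monitor bleaching
#' caused by repeated imaging), a constant background is added to every
#' trace, and independent Gaussian noise is added per frame.
#'
#' The whole-nucleus trace accounts for energy loss: the signal destroyed
#' by the bleach pulse is removed permanently from the nuclear total.
#' \code{bleachSpotFraction} is the fraction of total nuclear fluorescence
#' destroyed per unit bleach depth, i.e. the nuclear mean drops by
#' \code{bleachSpotFraction * preBleachLevel * (1 - postBleachDepth)} at the
#' bleach. The default 0.005 corresponds to a small confocal bleach spot
#' relative to the nuclear cross-section.
#'
#' @slot mobileFraction fraction of fluorophores free to exchange, in [0, 1].
#' @slot halfTime recovery half-time in seconds, > 0.
#' @slot postBleachDepth fraction of the pre-bleach signal remaining
#'   immediately after the bleach, in [0, 1).
#' @slot monitorBleachRate acquisition bleaching rate per second, >= 0.
#' @slot backgroundLevel additive background, intensity units >= 0.
#' @slot noiseSd Gaussian noise standard deviation, intensity units >= 0.
#' @slot nPre number of pre-bleach frames, >= 1.
#' @slot nPost number of post-bleach frames, >= 2.
#' @slot frameInterval seconds between frames, > 0.
#' @slot preBleachLevel pre-bleach mean intensity of the bleached region.
#' @slot bleachSpotFraction fraction of total nuclear signal removed by the
#'   bleach per unit depth, in [0, 0.5).
#' @slot seed integer seed; every generator call is deterministic given it.
#'
#' @seealso [generateFrapSeries()], [generateFrapStack()]
#' @export
setClass("FrapGroundTruth",
    slots = c(
        mobileFraction     = "numeric",
        halfTime           = "numeric",
        postBleachDepth    = "numeric",
        monitorBleachRate  = "numeric",
        backgroundLevel    = "numeric",
        noiseSd            = "numeric",
        nPre               = "integer",
        nPost              = "integer",
        frameInterval      = "numeric",
        preBleachLevel     = "numeric",
        bleachSpotFraction = "numeric",
        seed               = "integer"
    )
)

setValidity("FrapGroundTruth", function(object) {
    msg <- character()
    chk <- function(ok, text) if (!isTRUE(ok)) msg <<- c(msg, text)
    sc  <- function(x) length(x) == 1L && is.finite(x)
    chk(sc(object@mobileFraction) && object@mobileFraction >= 0 &&
            object@mobileFraction <= 1,
        "mobileFraction must be a single value in [0, 1]")
    chk(sc(object@halfTime) && object@halfTime > 0,
        "halfTime must be a single value > 0 (seconds)")
    chk(sc(object@postBleachDepth) && object@postBleachDepth >= 0 &&
            object@postBleachDepth < 1,
        "postBleachDepth must be in [0, 1)")
    chk(sc(object@monitorBleachRate) && object@monitorBleachRate >= 0,
        "monitorBleachRate must be >= 0 (per second)")
    chk(sc(object@backgroundLevel) && object@backgroundLevel >= 0,
        "backgroundLevel must be >= 0")
    chk(sc(object@noiseSd) && object@noiseSd >= 0, "noiseSd must be >= 0")
    chk(length(object@nPre) == 1L && object@nPre >= 1L, "nPre must be >= 1")
    chk(length(object@nPost) == 1L && object@nPost >= 2L, "nPost must be >= 2")
    chk(sc(object@frameInterval) && object@frameInterval > 0,
        "frameInterval must be > 0 (seconds)")
    chk(sc(object@preBleachLevel) && object@preBleachLevel > 0,
        "preBleachLevel must be > 0")
    chk(sc(object@bleachSpotFraction) && object@bleachSpotFraction >= 0 &&
            object@bleachSpotFraction < 0.5,
        "bleachSpotFraction must be in [0, 0.5)")
    chk(length(object@seed) == 1L && !is.na(object@seed),
        "seed must be a single non-missing integer")
    if (length(msg)) msg else TRUE
})

#' Construct a FrapGroundTruth
#'
#' Defaults reproduce the acquisition layout of a single-nucleolus confocal
#' FRAP protocol: 3 pre-scans, 97 post-bleach frames captured every 1 s,
#' bleach depth 0.4 of the pre-bleach level.
#'
#' @param seed integer seed (mandatory; generators hold no global state).
#' @param mobileFraction,halfTime,postBleachDepth,monitorBleachRate
#'   recovery-model parameters, see \linkS4class{FrapGroundTruth}.
#' @param backgroundLevel,noiseSd additive background and Gaussian noise SD.
#' @param nPre,nPost,frameInterval acquisition layout.
#' @param preBleachLevel,bleachSpotFraction intensity scale and the fraction
#'   of total nuclear signal destroyed by the bleach.
#' @return a validated \linkS4class{FrapGroundTruth}.
#' @examples
#' FrapGroundTruth(seed = 1, mobileFraction = 0.89, halfTime = 4.3)
#' @export
FrapGroundTruth <- function(seed,
                            mobileFraction = 0.89,
                            halfTime = 4.3,
                            postBleachDepth = 0.4,
                            monitorBleachRate = 0,
                            backgroundLevel = 50,
                            noiseSd = 0,
                            nPre = 3L,
                            nPost = 97L,
                            frameInterval = 1,
                            preBleachLevel = 1000,
                            bleachSpotFraction = 0.005) {
    if (missing(seed))
        stop("seed is mandatory: generators have no global random state")
    new("FrapGroundTruth",
        mobileFraction = as.numeric(mobileFraction),
        halfTime = as.numeric(halfTime),
        postBleachDepth = as.numeric(postBleachDepth),
        monitorBleachRate = as.numeric(monitorBleachRate),
        backgroundLevel = as.numeric(backgroundLevel),
        noiseSd = as.numeric(noiseSd),
        nPre = as.integer(nPre),
        nPost = as.integer(nPost),
        frameInterval = as.numeric(frameInterval),
        preBleachLevel = as.numeric(preBleachLevel),
        bleachSpotFraction = as.numeric(bleachSpotFraction),
        seed = as.integer(seed))
}

## ---- ground truth for the fixed-cell image simulator -----------------------

#' Ground truth for a simulated multi-channel nuclei image
#'
#' Describes one synthetic fixed-cell field: non-overlapping nuclear disks
#' (none touching the image border), each containing nucleolar disks that
#' fit entirely inside the nucleus. Three channels are rendered: a DNA
#' counterstain (filled nuclei), a nucleolar marker (nucleolar disks only)
#' and a target channel whose nucleolar pixels are \code{trueRatio} times
#' brighter than the nucleoplasm. Gaussian blur then Gaussian noise are
#' applied per channel.
#'
#' @slot nCells number of nuclei to place.
#' @slot nucleusRadius nuclear disk radius, pixels.
#' @slot nucleoliPerCell nucleoli per nucleus.
#' @slot nucleolusRadius nucleolar disk radius, pixels.
#' @slot nucleoplasmIntensity target-channel nucleoplasmic level.
#' @slot trueRatio nucleolar/nucleoplasmic mean ratio of the target channel,
#'   > 0.
#' @slot markerIntensity nucleolar-marker level inside nucleoli.
#' @slot dnaIntensity DNA-channel level inside nuclei.
#' @slot blurSigma Gaussian blur sigma, pixels >= 0.
#' @slot noiseSd additive Gaussian noise SD, intensity units >= 0.
#' @slot imageShape image size, c(rows, cols) pixels.
#' @slot seed integer seed.
#' @seealso [generateNucleiImage()]
#' @export
setClass("ImageGroundTruth",
    slots = c(
        nCells               = "integer",
        nucleusRadius        = "numeric",
        nucleoliPerCell      = "integer",
        nucleolusRadius      = "numeric",
        nucleoplasmIntensity = "numeric",
        trueRatio            = "numeric",
        markerIntensity      = "numeric",
        dnaIntensity         = "numeric",
        blurSigma            = "numeric",
        noiseSd              = "numeric",
        imageShape           = "integer",
        seed                 = "integer"
    )
)

setValidity("ImageGroundTruth", function(object) {
    msg <- character()
    chk <- function(ok, text) if (!isTRUE(ok)) msg <<- c(msg, text)
    chk(object@nCells >= 1L, "nCells must be >= 1")
    chk(object@nucleusRadius >= 3, "nucleusRadius must be >= 3 px")
    chk(object@nucleoliPerCell >= 0L, "nucleoliPerCell must be >= 0")
    chk(object@nucleolusRadius >= 1, "nucleolusRadius must be >= 1 px")
    chk(object@nucleolusRadius + 2 <= object@nucleusRadius,
        "nucleolusRadius: nucleoli must fit inside the nucleus (radius + 2 <= nucleusRadius)")
    chk(object@nucleoplasmIntensity > 0, "nucleoplasmIntensity must be > 0")
    chk(object@trueRatio > 0, "trueRatio must be > 0")
    chk(object@markerIntensity > 0, "markerIntensity must be > 0")
    chk(object@dnaIntensity > 0, "dnaIntensity must be > 0")
    chk(object@blurSigma >= 0, "blurSigma must be >= 0")
    chk(object@noiseSd >= 0, "noiseSd must be >= 0")
    chk(length(object@imageShape) == 2L && all(object@imageShape >= 16L),
        "imageShape must be two dimensions >= 16 px")
    chk(2 * object@nucleusRadius + 4 < min(object@imageShape),
        "imageShape: a nucleus must fit without touching the border")
    chk(length(object@seed) == 1L && !is.na(object@seed),
        "seed must be a single non-missing integer")
    if (length(msg)) msg else TRUE
})

#' Construct an ImageGroundTruth
#'
#' Defaults emulate a moderately crowded 512 x 512 field of cultured cells:
#' 20 nuclei of radius 30 px with two 8 px nucleoli each, a nucleolar
#' enrichment of 2.5, 1 px optical blur, and noise at 2\% of the
#' nucleoplasmic level.
#'
#' @param seed integer seed (mandatory).
#' @param nCells,nucleusRadius,nucleoliPerCell,nucleolusRadius geometry.
#' @param nucleoplasmIntensity,trueRatio,markerIntensity,dnaIntensity
#'   channel intensities; \code{trueRatio} is the nucleolar/nucleoplasmic
#'   mean ratio of the target channel.
#' @param blurSigma,noiseSd optics and noise.
#' @param imageShape image size in pixels, c(rows, cols).
#' @return a validated \linkS4class{ImageGroundTruth}.
#' @examples
#' ImageGroundTruth(seed = 7, trueRatio = 3)
#' @export
ImageGroundTruth <- function(seed,
                             nCells = 20L,
                             nucleusRadius = 30,
                             nucleoliPerCell = 2L,
                             nucleolusRadius = 8,
                             nucleoplasmIntensity = 100,
                             trueRatio = 2.5,
                             markerIntensity = 500,
                             dnaIntensity = 300,
                             blurSigma = 1,
                             noiseSd = 2,
                             imageShape = c(512L, 512L)) {
    if (missing(seed))
        stop("seed is mandatory: generators have no global random state")
    new("ImageGroundTruth",
        nCells = as.integer(nCells),
        nucleusRadius = as.numeric(nucleusRadius),
        nucleoliPerCell = as.integer(nucleoliPerCell),
        nucleolusRadius = as.numeric(nucleolusRadius),
        nucleoplasmIntensity = as.numeric(nucleoplasmIntensity),
        trueRatio = as.numeric(trueRatio),
        markerIntensity = as.numeric(markerIntensity),
        dnaIntensity = as.numeric(dnaIntensity),
        blurSigma = as.numeric(blurSigma),
        noiseSd = as.numeric(noiseSd),
        imageShape = as.integer(imageShape),
        seed = as.integer(seed))
}

## ---- FRAP data containers ---------------------------------------------------

#' Raw FRAP region traces
#'
#' Per-frame mean intensities of the three regions recorded during a FRAP
#' acquisition: the bleached region (here a single nucleolus), the whole
#' nucleus, and a background region, with the acquisition time base and the
#' number of pre-bleach frames.
#'
#' @slot timeS acquisition times in seconds, strictly increasing.
#' @slot roiMean bleached-region mean intensity per frame.
#' @slot totalMean whole-nucleus mean intensity per frame.
#' @slot backgroundMean background mean intensity per frame.
#' @slot nPre number of pre-bleach frames (>= 1).
#' @slot metadata list of extra columns / acquisition metadata carried
#'   through file round-trips.
#' @slot truth the paired \linkS4class{FrapGroundTruth} for synthetic
#'   series, or NULL for measured data.
#' @seealso [readFrapCsv()], [analyzeFrap()]
#' @export
setClass("FrapSeries",
    slots = c(
        timeS          = "numeric",
        roiMean        = "numeric",
        totalMean      = "numeric",
        backgroundMean = "numeric",
        nPre           = "integer",
        metadata       = "list",
        truth          = "ANY"
    ),
    prototype = prototype(metadata = list(), truth = NULL)
)

setValidity("FrapSeries", function(object) {
    n <- length(object@timeS)
    msg <- character()
    if (length(object@roiMean) != n || length(object@totalMean) != n ||
            length(object@backgroundMean) != n)
        msg <- c(msg, "all traces must have the same length as timeS")
    if (object@nPre < 1L)
        msg <- c(msg, "nPre must be >= 1")
    if (n < object@nPre + 2L)
        msg <- c(msg, "series must have at least nPre + 2 frames")
    if (!all(is.finite(object@timeS)) || any(diff(object@timeS) <= 0))
        msg <- c(msg, "timeS must be finite and strictly increasing")
    if (!all(is.finite(c(object@roiMean, object@totalMean,
                         object@backgroundMean))))
        msg <- c(msg, "intensities must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct a FrapSeries
#'
#' @param timeS,roiMean,totalMean,backgroundMean per-frame vectors.
#' @param nPre number of pre-bleach frames.
#' @param metadata optional list of extra per-frame columns or metadata.
#' @param truth optional paired \linkS4class{FrapGroundTruth}.
#' @return a validated \linkS4class{FrapSeries}.
#' @export
FrapSeries <- function(timeS, roiMean, totalMean, backgroundMean,
                       nPre, metadata = list(), truth = NULL) {
    new("FrapSeries", timeS = as.numeric(timeS),
        roiMean = as.numeric(roiMean), totalMean = as.numeric(totalMean),
        backgroundMean = as.numeric(backgroundMean),
        nPre = as.integer(nPre), metadata = metadata, truth = truth)
}

#' Corrected, pre-bleach-normalized FRAP recovery curve
#'
#' Output of [normalizeFrap()]: background-subtracted, acquisition-corrected
#' intensities divided by the pre-bleach mean F_pre, with time re-zeroed at
#' the first post-bleach frame. Holds the three summary intensities of the
#' mobile-fraction formula: \code{fPre} (pre-bleach mean, 1 by
#' construction), \code{fPost} (first post-bleach value) and \code{fEnd}
#' (mean over the terminal plateau window).
#'
#' @slot timeS time in seconds; 0 at the first post-bleach frame.
#' @slot value dimensionless normalized intensity per frame.
#' @slot nPre number of pre-bleach frames.
#' @slot fPre normalized pre-bleach mean (= 1, retained for audit).
#' @slot fPost value at the first post-bleach frame.
#' @slot fEnd mean of the last \code{endWindow} frames.
#' @slot endWindow number of terminal frames averaged for fEnd.
#' @slot preLevel the raw (un-normalized) F_pre, for audit.
#' @export
setClass("NormalizedCurve",
    slots = c(
        timeS     = "numeric",
        value     = "numeric",
        nPre      = "integer",
        fPre      = "numeric",
        fPost     = "numeric",
        fEnd      = "numeric",
        endWindow = "integer",
        preLevel  = "numeric"
    )
)

setValidity("NormalizedCurve", function(object) {
    msg <- character()
    nPost <- length(object@value) - object@nPre
    if (length(object@value) != length(object@timeS))
        msg <- c(msg, "value and timeS must have the same length")
    if (abs(mean(object@value[seq_len(object@nPre)]) - 1) > 1e-12)
        msg <- c(msg, "pre-bleach mean must equal 1 within 1e-12")
    if (!isTRUE(all.equal(object@fPost, object@value[object@nPre + 1L],
                          tolerance = 1e-12)))
        msg <- c(msg, "fPost must equal the first post-bleach value")
    if (object@endWindow > nPost)
        msg <- c(msg, "endWindow cannot exceed the number of post-bleach frames")
    if (length(msg)) msg else TRUE
})

#' Per-cell FRAP estimate
#'
#' Mobile fraction and recovery half-time for one cell, with fit
#' diagnostics. \code{method} is \code{"exp_fit"} (least-squares single
#' exponential) or \code{"interpolation"} (model-free half-recovery
#' crossing). The mobile fraction is reported even when the half-time fit
#' fails (\code{converged = FALSE}, interpolation fallback).
#'
#' @slot mobileFraction M_f = (F_end - F_post)/(F_pre - F_post),
#'   dimensionless; not clipped to [0, 1].
#' @slot halfTimeS recovery half-time T_1/2 in seconds.
#' @slot method half-time estimator used.
#' @slot fitRMSE root-mean-square residual of the exponential fit
#'   (0 for interpolation).
#' @slot converged whether the exponential fit converged.
#' @slot fPre,fPost,fEnd,endWindow the normalized summary intensities.
#' @export
setClass("FrapEstimate",
    slots = c(
        mobileFraction = "numeric",
        halfTimeS      = "numeric",
        method         = "character",
        fitRMSE        = "numeric",
        converged      = "logical",
        fPre           = "numeric",
        fPost          = "numeric",
        fEnd           = "numeric",
        endWindow      = "integer"
    )
)

setValidity("FrapEstimate", function(object) {
    msg <- character()
    if (!object@method %in% c("exp_fit", "interpolation"))
        msg <- c(msg, "method must be 'exp_fit' or 'interpolation'")
    if (isTRUE(object@converged) && !is.na(object@halfTimeS) &&
            object@halfTimeS <= 0)
        msg <- c(msg, "halfTimeS must be > 0 when converged")
    if (length(msg)) msg else TRUE
})

## ---- segmentation container -------------------------------------------------

#' Labeled nuclear and nucleolar masks
#'
#' Segmentation result for one field: an integer nuclear label image
#' (0 = background, k = cell k, labels consecutive from 1, border-touching
#' nuclei removed), a binary nucleolar mask restricted to nuclear pixels,
#' and the assignment of each 8-connected nucleolar component to its cell.
#'
#' @slot nuclearLabels integer matrix of nuclear labels.
#' @slot nucleolarMask logical matrix; TRUE on nucleolar pixels.
#' @slot assignment data.frame with columns \code{component} and
#'   \code{cell}: which nucleus each nucleolar component lies in.
#' @slot flaggedCells integer vector of cells whose marker signal was too
#'   uniform to threshold (empty nucleolar set, flagged not fatal).
#' @seealso [nuclearMask()], [nucleolarMask()], [compartmentRatio()]
#' @export
setClass("LabeledMasks",
    slots = c(
        nuclearLabels = "matrix",
        nucleolarMask = "matrix",
        assignment    = "data.frame",
        flaggedCells  = "integer"
    )
)

setValidity("LabeledMasks", function(object) {
    msg <- character()
    lab <- object@nuclearLabels
    nuo <- object@nucleolarMask
    if (!identical(dim(lab), dim(nuo)))
        msg <- c(msg, "nuclearLabels and nucleolarMask must have identical dimensions")
    else if (any(nuo & lab == 0L))
        msg <- c(msg, "every nucleolar pixel must lie inside a labeled nucleus")
    labs <- sort(unique(as.integer(lab[lab > 0L])))
    if (length(labs) && !identical(labs, seq_along(labs)))
        msg <- c(msg, "nuclear labels must be consecutive from 1")
    if (length(labs)) {
        border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
        if (any(border > 0L))
            msg <- c(msg, "no nucleus may touch the image border")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a LabeledMasks
#' @param nuclearLabels integer label matrix.
#' @param nucleolarMask logical matrix of nucleolar pixels.
#' @param assignment data.frame(component, cell).
#' @param flaggedCells integer vector of cells without a usable threshold.
#' @return a validated \linkS4class{LabeledMasks}.
#' @export
LabeledMasks <- function(nuclearLabels, nucleolarMask,
                         assignment = data.frame(component = integer(),
                                                 cell = integer()),
                         flaggedCells = integer()) {
    storage.mode(nuclearLabels) <- "integer"
    mode(nucleolarMask) <- "logical"
    new("LabeledMasks", nuclearLabels = nuclearLabels,
        nucleolarMask = nucleolarMask, assignment = assignment,
        flaggedCells = as.integer(flaggedCells))
}
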