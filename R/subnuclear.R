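#' @include AllClasses.R
NULL

#' Otsu threshold of a set of pixel intensities
#'
#' Histogram-based Otsu threshold (maximum between-class variance) over an
#' arbitrary collection of pixel values, e.g. the pixels of one nucleus.
#' Works on any numeric vector, unlike whole-image thresholders; agreement
#' with EBImage's image-level Otsu is within one histogram bin.
#'
#' @param x numeric vector of intensities.
#' @param levels number of histogram bins.
#' @return the threshold; foreground is \code{x > threshold}.
#' @export
otsuThreshold <- function(x, levels = 256L) {
    x <- x[is.finite(x)]
    if (!length(x)) stop("no finite values to threshold")
    lo <- min(x); hi <- max(x)
    if (hi - lo <= .Machine$double.eps * max(1, abs(hi)))
        stop("cannot threshold: intensities are uniform")
    breaks <- seq(lo, hi, length.out = levels + 1L)
    mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
    counts <- tabulate(pmin(pmax(findInterval(x, breaks,
                                              rightmost.closed = TRUE), 1L),
                            levels), levels)
    w <- counts / sum(counts)
    w0 <- cumsum(w)
    mu <- cumsum(w * mids)
    muT <- mu[levels]
    w1 <- 1 - w0
    sigmaB <- (muT * w0 - mu)^2 / (w0 * w1)
    sigmaB[!is.finite(sigmaB)] <- -Inf
    breaks[which.max(sigmaB) + 1L]  # upper edge of the best split bin
}

## 8-connected labeling: EBImage::bwlabel is 4-connected, so diagonally
## adjacent components are merged afterwards with a union-find
label8 <- function(mask) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    storage.mode(lab) <- "integer"
    nLab <- max(lab)
    if (nLab == 0L) return(lab)
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
        cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),  # \ diag
        cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L])))  # / diag
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    parent <- seq_len(nLab)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(nLab), find, integer(1L))
    relab <- match(root, sort(unique(root)))
    out <- lab
    out[lab > 0L] <- relab[lab[lab > 0L]]
    out
}

dropLabels <- function(lab, drop) {
    if (length(drop)) lab[lab %in% drop] <- 0L
    keep <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], keep)
    lab
}

borderLabels <- function(lab) {
    unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
}

## binary erosion by a disc of the given radius (0 = identity)
erodeMask <- function(mask, radius) {
    if (radius <= 0 || !any(mask)) return(mask)
    EBImage::imageData(EBImage::erode(
        EBImage::Image(mask * 1),
        EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc"))) > 0
}

#' Segment nuclei from a DNA counterstain channel
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, removal of
#' small and border-touching components, and 8-connected labeling. This is
#' the "DNA mask" defining the nuclear area of each cell.
#'
#' @param dna single-channel numeric matrix.
#' @param sigma smoothing sigma in pixels (0 disables smoothing).
#' @param minArea minimum nucleus area in pixels.
#' @return integer label matrix (0 = background, k = cell k; labels
#'   consecutive from 1).
#' @export
nuclearMask <- function(dna, sigma = 1, minArea = 200L) {
    if (!is.matrix(dna)) stop("dna must be a single-channel matrix")
    if (stats::sd(dna) == 0)
        stop("segmentation error: DNA channel has zero variance")
    sm <- if (sigma > 0)
        EBImage::imageData(EBImage::gblur(EBImage::Image(dna), sigma = sigma))
    else dna
    mask <- sm > otsuThreshold(as.numeric(sm))
    mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
    lab <- label8(mask)
    if (max(lab) == 0L)
        stop("segmentation error: no foreground found in DNA channel")
    sizes <- tabulate(lab[lab > 0L], max(lab))
    drop <- unique(c(which(sizes < minArea), borderLabels(lab)))
    lab <- dropLabels(lab, drop[drop > 0L])
    if (max(lab) == 0L)
        stop("segmentation error: no nucleus survived area/border filtering")
    lab
}

#' Segment nucleoli from a marker channel within labeled nuclei
#'
#' The nucleolar mask always comes from a dedicated marker channel (the
#' surrogate-marker principle), never from the target channel being
#' quantified. Within each nucleus an Otsu threshold is computed from that
#' nucleus' marker pixels only, making the mask robust to cell-to-cell
#' staining variation. Components smaller than \code{minArea} pixels are
#' removed; pixels outside nuclei are never included. Nuclei whose marker
#' signal is too uniform to threshold are flagged (empty nucleolar set for
#' that cell), not fatal.
#'
#' @param marker single-channel numeric matrix.
#' @param nuclei integer nuclear label matrix from [nuclearMask()].
#' @param minArea minimum nucleolar component area in pixels.
#' @return a \linkS4class{LabeledMasks}.
#' @export
nucleolarMask <- function(marker, nuclei, minArea = 10L) {
    if (!identical(dim(marker), dim(nuclei)))
        stop("marker and nuclei label image must have identical dimensions")
    mask <- matrix(FALSE, nrow(marker), ncol(marker))
    flagged <- integer()
    nCells <- max(0L, max(nuclei))
    for (k in seq_len(nCells)) {
        idx <- which(nuclei == k)
        px <- marker[idx]
        rng <- diff(range(px))
        if (rng <= 1e-9 * max(1, abs(max(px)))) {
            flagged <- c(flagged, k)
            next
        }
        mask[idx[px > otsuThreshold(px)]] <- TRUE
    }
    comp <- label8(mask)
    if (max(comp) > 0L) {
        sizes <- tabulate(comp[comp > 0L], max(comp))
        comp <- dropLabels(comp, which(sizes < minArea))
    }
    mask <- comp > 0L
    assignment <- if (max(comp) > 0L) {
        do.call(rbind, lapply(seq_len(max(comp)), function(cc) {
            cells <- nuclei[comp == cc]
            data.frame(component = cc,
                       cell = as.integer(names(which.max(table(cells)))))
        }))
    } else data.frame(component = integer(), cell = integer())
    LabeledMasks(nuclearLabels = nuclei, nucleolarMask = mask,
                 assignment = assignment, flaggedCells = flagged)
}

#' Overlap fractions between two binary masks
#'
#' Reports all three common overlap metrics, since "overlap" alone is
#' ambiguous: the intersection as a fraction of mask A, of mask B, and of
#' their union (Jaccard index).
#'
#' @param maskA,maskB logical matrices of identical shape.
#' @return named numeric vector: \code{overlap_a} (|A∩B|/|A|),
#'   \code{overlap_b} (|A∩B|/|B|), \code{jaccard} (|A∩B|/|A∪B|); NA where
#'   the denominator is empty.
#' @export
maskOverlap <- function(maskA, maskB) {
    if (!identical(dim(maskA), dim(maskB)))
        stop("masks must have identical dimensions")
    maskA <- maskA > 0; maskB <- maskB > 0
    i <- sum(maskA & maskB)
    frac <- function(d) if (d > 0) i / d else NA_real_
    c(overlap_a = frac(sum(maskA)), overlap_b = frac(sum(maskB)),
      jaccard = frac(sum(maskA | maskB)))
}

#' Per-cell nucleolar/nucleoplasmic intensity ratio
#'
#' For each cell the nucleolar mean is the mean target intensity over that
#' cell's nucleolar pixels and the nucleoplasmic mean is the mean over the
#' nuclear pixels minus the nucleolar pixels (mask subtraction); the ratio
#' is their quotient. By default the field background — the median target
#' intensity outside all nuclei — is subtracted from both means first,
#' which makes the ratio invariant under multiplicative rescaling of the
#' channel. Cells with an empty nucleolar set get a row with a missing
#' ratio.
#'
#' @param target single-channel numeric matrix.
#' @param masks a \linkS4class{LabeledMasks}.
#' @param subtractBackground subtract the outside-nuclei median first.
#' @param edgeErode rim width in pixels excluded from intensity means at
#'   the nucleus/background boundary (and half of it at the nucleolar
#'   boundary). Optical blur dilutes boundary pixels with the adjacent
#'   compartment, biasing compartment means; excluding a rim of roughly
#'   twice the blur sigma removes that bias. Areas and the mask partition
#'   always use the full masks; set 0 to measure over them too.
#' @return data.frame, one row per cell: cell_id, nucleolar_mean,
#'   nucleoplasmic_mean, ratio, nucleolar_area_px, nuclear_area_px,
#'   nuclear_mean.
#' @export
compartmentRatio <- function(target, masks, subtractBackground = TRUE,
                             edgeErode = 2L) {
    validObject(masks)
    lab <- masks@nuclearLabels
    if (!identical(dim(target), dim(lab)))
        stop("target and masks must have identical dimensions")
    bg <- if (subtractBackground) stats::median(target[lab == 0L]) else 0
    nCells <- max(0L, max(lab))
    nucCore <- erodeMask(lab > 0L, edgeErode)
    nuoCore <- erodeMask(masks@nucleolarMask, ceiling(edgeErode / 2))
    rows <- lapply(seq_len(nCells), function(k) {
        nuc <- lab == k
        nucleolar <- nuc & masks@nucleolarMask
        nucleoplasm <- nuc & !masks@nucleolarMask
        ## measurement sets: rim-eroded, falling back to the full masks
        ## when erosion empties them (small objects)
        mNucleolar <- nucleolar & nuoCore
        if (!any(mNucleolar)) mNucleolar <- nucleolar
        mNucleoplasm <- nucleoplasm & nucCore
        if (!any(mNucleoplasm)) mNucleoplasm <- nucleoplasm
        mNuclear <- nuc & nucCore
        if (!any(mNuclear)) mNuclear <- nuc
        nMean <- if (any(mNucleolar)) mean(target[mNucleolar]) - bg
                 else NA_real_
        pMean <- mean(target[mNucleoplasm]) - bg
        data.frame(cell_id = k,
                   nucleolar_mean = nMean,
                   nucleoplasmic_mean = pMean,
                   ratio = if (!is.na(nMean) && pMean > 0) nMean / pMean
                           else NA_real_,
                   nucleolar_area_px = sum(nucleolar),
                   nuclear_area_px = sum(nuc),
                   nuclear_mean = mean(target[mNuclear]) - bg)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-cell nucleolar area
#'
#' Total nucleolar pixel count per cell and its fraction of the nuclear
#' area.
#'
#' @param masks a \linkS4class{LabeledMasks}.
#' @return data.frame: cell_id, nucleolar_area_px, nuclear_area_px,
#'   area_fraction.
#' @export
nucleolarArea <- function(masks) {
    validObject(masks)
    lab <- masks@nuclearLabels
    nCells <- max(0L, max(lab))
    nuclear <- tabulate(lab[lab > 0L], nCells)
    nucleolar <- tabulate(lab[masks@nucleolarMask], nCells)
    data.frame(cell_id = seq_len(nCells),
               nucleolar_area_px = nucleolar,
               nuclear_area_px = nuclear,
               area_fraction = nucleolar / nuclear)
}

#' Per-cell nuclear mean intensity of a channel
#'
#' Mean intensity of an arbitrary channel over each cell's nuclear pixels
#' (e.g. a nascent-RNA label quantified over the DNA-defined nuclear
#' area). No background subtraction is applied.
#'
#' @param channel single-channel numeric matrix.
#' @param masks a \linkS4class{LabeledMasks}.
#' @return data.frame: cell_id, nuclear_mean.
#' @export
nuclearMeanIntensity <- function(channel, masks) {
    validObject(masks)
    lab <- masks@nuclearLabels
    if (!identical(dim(channel), dim(lab)))
        stop("channel and masks must have identical dimensions")
    nCells <- max(0L, max(lab))
    data.frame(cell_id = seq_len(nCells),
               nuclear_mean = vapply(seq_len(nCells), function(k)
                   mean(channel[lab == k]), numeric(1L)))
}

#' Quantify one multi-channel field end to end
#'
#' Convenience pipeline: nuclear segmentation on the DNA channel,
#' per-nucleus nucleolar segmentation on the marker channel, then
#' compartment ratios on the target channel.
#'
#' @param channels named list of channel matrices (or output of
#'   [generateNucleiImage()]'s \code{channels} element).
#' @param dnaChannel,markerChannel,targetChannel channel names or indices.
#' @param sigma,minNucleusArea,minNucleolusArea segmentation parameters.
#' @param subtractBackground passed to [compartmentRatio()].
#' @return a list: \code{masks} (\linkS4class{LabeledMasks}) and
#'   \code{measurements} (per-cell data.frame).
#' @export
quantifyField <- function(channels, dnaChannel = "dna",
                          markerChannel = "marker",
                          targetChannel = "target",
                          sigma = 1, minNucleusArea = 200L,
                          minNucleolusArea = 10L,
                          subtractBackground = TRUE) {
    nuclei <- nuclearMask(channels[[dnaChannel]], sigma = sigma,
                          minArea = minNucleusArea)
    masks <- nucleolarMask(channels[[markerChannel]], nuclei,
                           minArea = minNucleolusArea)
    list(masks = masks,
         measurements = compartmentRatio(channels[[targetChannel]], masks,
                                         subtractBackground = subtractBackground))
}
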