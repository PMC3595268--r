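#' @include synthetic-frap.R
NULL

## place n disk centers with pairwise center distance > minDist inside
## [lo, hi] x [lo, hi]; bounded rejection sampling
placeCenters <- function(n, lo, hi, minDist, maxAttempts = 500L * n) {
    centers <- matrix(numeric(0), ncol = 2L)
    attempts <- 0L
    while (nrow(centers) < n) {
        attempts <- attempts + 1L
        if (attempts > maxAttempts)
            stop("could not place ", n, " non-overlapping disks after ",
                 maxAttempts, " attempts; geometry infeasible")
        cand <- stats::runif(2L, lo, hi)
        if (nrow(centers) == 0L ||
                all(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2)) >
                        minDist))
            centers <- rbind(centers, cand)
    }
    centers
}

#' Simulate a multi-channel fixed-cell field with known ground truth
#'
#' Renders the three channels quantified by the fixed-cell pipeline:
#' a DNA counterstain (uniform disks at the nuclear positions), a
#' nucleolar marker (uniform disks at the nucleolar positions only), and a
#' target channel equal to \code{nucleoplasmIntensity} inside nuclei with
#' nucleolar pixels at \code{trueRatio * nucleoplasmIntensity}. Each
#' channel is then Gaussian-blurred (\code{blurSigma}) and Gaussian noise
#' (\code{noiseSd}) is added. Nuclei never overlap or touch the image
#' border; nucleoli lie entirely inside their nucleus. Placement uses
#' bounded rejection sampling and fails with an error if the geometry is
#' infeasible.
#'
#' @param truth an \linkS4class{ImageGroundTruth}.
#' @param ... unused.
#' @return a list: \code{channels} (named list of numeric matrices
#'   \code{dna}, \code{marker}, \code{target}), \code{cells} (per-cell
#'   ground-truth data.frame: cell_id, center_row, center_col,
#'   nuclear_area_px, nucleolar_area_px, true_ratio), \code{truthMasks}
#'   (the noise-free label/mask matrices used for rendering) and
#'   \code{truth}.
#' @examples
#' field <- generateNucleiImage(ImageGroundTruth(seed = 3, nCells = 5L))
#' field$cells
#' @export
setMethod("generateNucleiImage", "ImageGroundTruth", function(truth, ...) {
    validObject(truth)
    shape <- truth@imageShape
    rN <- truth@nucleusRadius
    rn <- truth@nucleolusRadius
    withr::with_seed(truth@seed, {
        ## margin 2 px from the border, gap >= 3 px between nuclei
        centers <- placeCenters(truth@nCells, lo = rN + 2,
                                hi = min(shape) - 1 - rN - 2,
                                minDist = 2 * rN + 3)
        nuclearLabels <- matrix(0L, shape[1L], shape[2L])
        nucleolarMask <- matrix(FALSE, shape[1L], shape[2L])
        cells <- vector("list", truth@nCells)
        for (k in seq_len(truth@nCells)) {
            nucDisk <- rasterDisk(shape, centers[k, ], rN)
            nuclearLabels[nucDisk] <- k
            nucleoliCenters <- matrix(numeric(0), ncol = 2L)
            if (truth@nucleoliPerCell > 0L) {
                maxOff <- rN - rn - 1.5
                tries <- 0L
                while (nrow(nucleoliCenters) < truth@nucleoliPerCell) {
                    tries <- tries + 1L
                    if (tries > 500L * truth@nucleoliPerCell)
                        stop("could not place ", truth@nucleoliPerCell,
                             " nucleoli inside a nucleus of radius ", rN,
                             "; geometry infeasible")
                    ang <- stats::runif(1L, 0, 2 * pi)
                    rad <- maxOff * sqrt(stats::runif(1L))
                    cand <- centers[k, ] + rad * c(cos(ang), sin(ang))
                    if (nrow(nucleoliCenters) == 0L ||
                            all(sqrt(rowSums((nucleoliCenters -
                                 rep(cand, each = nrow(nucleoliCenters)))^2)) >
                                2 * rn + 1))
                        nucleoliCenters <- rbind(nucleoliCenters, cand)
                }
                for (q in seq_len(nrow(nucleoliCenters)))
                    nucleolarMask[rasterDisk(shape, nucleoliCenters[q, ], rn)] <- TRUE
            }
            cells[[k]] <- data.frame(cell_id = k,
                                     center_row = centers[k, 1L],
                                     center_col = centers[k, 2L])
        }
        cells <- do.call(rbind, cells)
        cells$nuclear_area_px <- as.integer(tabulate(nuclearLabels[nuclearLabels > 0L],
                                                     truth@nCells))
        cells$nucleolar_area_px <- as.integer(
            tabulate(nuclearLabels[nucleolarMask], truth@nCells))
        cells$true_ratio <- truth@trueRatio

        dna    <- matrix(0, shape[1L], shape[2L])
        marker <- matrix(0, shape[1L], shape[2L])
        target <- matrix(0, shape[1L], shape[2L])
        inside <- nuclearLabels > 0L
        dna[inside] <- truth@dnaIntensity
        marker[nucleolarMask] <- truth@markerIntensity
        target[inside] <- truth@nucleoplasmIntensity
        target[nucleolarMask] <- truth@trueRatio * truth@nucleoplasmIntensity

        channels <- list(dna = dna, marker = marker, target = target)
        if (truth@blurSigma > 0)
            channels <- lapply(channels, function(ch)
                EBImage::imageData(EBImage::gblur(EBImage::Image(ch),
                                                  sigma = truth@blurSigma)))
        if (truth@noiseSd > 0)
            channels <- lapply(channels, function(ch)
                ch + matrix(stats::rnorm(length(ch), sd = truth@noiseSd),
                            nrow(ch), ncol(ch)))
        list(channels = channels, cells = cells,
             truthMasks = list(nuclearLabels = nuclearLabels,
                               nucleolarMask = nucleolarMask),
             truth = truth)
    })
})

truthToList <- function(truth) {
    nm <- slotNames(class(truth))
    stats::setNames(lapply(nm, function(s) slot(truth, s)), nm)
}

#' Simulate a two-condition fixed-cell experiment
#'
#' Generates \code{fieldsPerCondition} image fields for each of two
#' conditions ("control", "treated") that differ only through their
#' \linkS4class{ImageGroundTruth} parameters. Field seeds are derived
#' deterministically from each truth's seed (offset by field and condition
#' index) so the two conditions are statistically independent even when
#' their truths are identical — the configuration used for null
#' calibration of the downstream tests.
#'
#' @param control,treated \linkS4class{ImageGroundTruth} for each condition.
#' @param fieldsPerCondition number of fields per condition.
#' @param dir if non-NULL, directory where per-field multi-page TIFFs, a
#'   \code{manifest.csv} and JSON ground-truth sidecars are written.
#' @return a list: \code{fields} (named list of [generateNucleiImage()]
#'   results) and \code{manifest} (data.frame with one row per field:
#'   field_id, condition, seed, file).
#' @export
generateTwoConditionExperiment <- function(control, treated,
                                           fieldsPerCondition = 2L,
                                           dir = NULL) {
    validObject(control); validObject(treated)
    truths <- list(control = control, treated = treated)
    fields <- list()
    manifest <- list()
    for (ci in seq_along(truths)) {
        cond <- names(truths)[ci]
        for (f in seq_len(fieldsPerCondition)) {
            fieldSeed <- truths[[ci]]@seed +
                (ci - 1L) * fieldsPerCondition + (f - 1L)
            tr <- truths[[ci]]
            tr@seed <- as.integer(fieldSeed)
            id <- sprintf("%s_f%02d", cond, f)
            fields[[id]] <- generateNucleiImage(tr)
            file <- NA_character_
            if (!is.null(dir)) {
                if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
                file <- file.path(dir, paste0(id, ".tif"))
                writeImageChannels(fields[[id]]$channels, file, clip = TRUE)
                jsonlite::write_json(truthToList(tr),
                                     file.path(dir, paste0(id, ".json")),
                                     auto_unbox = TRUE, digits = NA)
            }
            manifest[[id]] <- data.frame(field_id = id, condition = cond,
                                         seed = fieldSeed, file = file,
                                         stringsAsFactors = FALSE)
        }
    }
    manifest <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
    if (!is.null(dir))
        utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                         row.names = FALSE)
    list(fields = fields, manifest = manifest)
}
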