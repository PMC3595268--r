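#' @include AllClasses.R
NULL

frapCsvColumns <- c("time_s", "roi_mean", "total_mean", "background_mean",
                    "is_prebleach")

#' Read a FRAP curve table
#'
#' Reads the standard FRAP CSV layout: columns \code{time_s},
#' \code{roi_mean}, \code{total_mean}, \code{background_mean} and
#' \code{is_prebleach} (0/1, pre-bleach frames first). Unknown columns are
#' preserved in the series metadata; the decimal separator is always the
#' point, independent of locale.
#'
#' @param path CSV file path.
#' @return a \linkS4class{FrapSeries}.
#' @export
readFrapCsv <- function(path) {
    if (!file.exists(path)) stop("FRAP CSV not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(frapCsvColumns, names(df))
    if (length(missing))
        stop("FRAP CSV schema error: missing column(s) ",
             paste(missing, collapse = ", "))
    pre <- df$is_prebleach
    nPre <- sum(pre == 1)
    if (nPre < 1L || any(pre[seq_len(nPre)] != 1) || any(pre[-seq_len(nPre)] != 0))
        stop("FRAP CSV schema error: is_prebleach must mark a leading block ",
             "of pre-bleach frames")
    extra <- df[setdiff(names(df), frapCsvColumns)]
    FrapSeries(timeS = df$time_s, roiMean = df$roi_mean,
               totalMean = df$total_mean, backgroundMean = df$background_mean,
               nPre = nPre,
               metadata = if (ncol(extra)) list(extra_columns = extra)
                          else list())
}

#' Write a FRAP series as a curve table
#'
#' Inverse of [readFrapCsv()]; extra columns carried in the metadata are
#' written back.
#'
#' @param series a \linkS4class{FrapSeries}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFrapCsv <- function(series, path) {
    df <- data.frame(time_s = series@timeS, roi_mean = series@roiMean,
                     total_mean = series@totalMean,
                     background_mean = series@backgroundMean,
                     is_prebleach = as.integer(
                         seq_along(series@timeS) <= series@nPre))
    if (!is.null(series@metadata$extra_columns))
        df <- cbind(df, series@metadata$extra_columns)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read a multi-page TIFF as a list of channel matrices
#'
#' Pages are returned in file order as numeric matrices
#' (page-per-channel layout). Integer TIFFs are read at their native
#' scale (\code{as.is}), so 8- and 16-bit files differ only by a
#' multiplicative factor — downstream ratios are unaffected.
#'
#' @param path TIFF file path.
#' @return a list: \code{channels} (list of numeric matrices) and
#'   \code{nPages}.
#' @export
readImageChannels <- function(path) {
    if (!file.exists(path)) stop("image file not found: ", path)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                          stop("cannot read TIFF '", path, "': ",
                               conditionMessage(e)))
    channels <- lapply(pages, function(p) {
        m <- as.matrix(p)
        storage.mode(m) <- "double"
        m
    })
    list(channels = channels, nPages = length(channels))
}

#' Write channel matrices as a multi-page TIFF
#'
#' One page per channel. For integer bit depths values must lie in
#' [0, 2^bits - 1] and are stored losslessly after rounding; with
#' \code{bits = 32} samples are stored as floating point.
#'
#' @param channels list of numeric matrices (or a single matrix).
#' @param path output path.
#' @param bits bits per sample: 8, 16 (integer) or 32 (float).
#' @param clip clip out-of-range values to the representable range instead
#'   of failing (used when storing noisy synthetic images, whose Gaussian
#'   noise can undershoot 0).
#' @return the path, invisibly.
#' @export
writeImageChannels <- function(channels, path, bits = 16L, clip = FALSE) {
    if (is.matrix(channels)) channels <- list(channels)
    if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32")
    if (bits == 32L) {
        tiff::writeTIFF(channels, path, bits.per.sample = 32L)
        return(invisible(path))
    }
    maxVal <- 2^bits - 1
    scaled <- lapply(channels, function(ch) {
        if (clip) ch <- pmin(pmax(ch, 0), maxVal)
        else if (any(ch < 0) || any(ch > maxVal))
            stop("channel values outside [0, ", maxVal, "] for ", bits,
                 "-bit output")
        round(ch) / maxVal
    })
    tiff::writeTIFF(scaled, path, bits.per.sample = bits)
    invisible(path)
}

#' Write / read a per-cell measurements table
#'
#' CSV round-trip for the per-cell tables produced by
#' [compartmentRatio()], [quantifyField()] and [analyzeFrapSet()].
#' \code{readMeasurements} checks that the named columns are present.
#'
#' @param measurements data.frame.
#' @param path CSV path.
#' @param required character vector of required column names.
#' @return \code{writeMeasurements}: the path, invisibly;
#'   \code{readMeasurements}: the data.frame.
#' @export
writeMeasurements <- function(measurements, path) {
    utils::write.csv(measurements, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMeasurements
#' @export
readMeasurements <- function(path, required = character()) {
    if (!file.exists(path)) stop("measurements file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("measurements schema error: missing column(s) ",
             paste(missing, collapse = ", "))
    df
}

#' Provenance record for a run
#'
#' Every pipeline run can be summarized as a JSON provenance record
#' holding the configuration, the package version and MD5 checksums of the
#' input files, sufficient to re-run the analysis bit-identically.
#'
#' @param config named list of run parameters (include the seed).
#' @param inputs character vector of input file paths.
#' @param path if non-NULL, write the record there as JSON.
#' @return the provenance record as a list, invisibly if written.
#' @export
writeProvenance <- function(config, inputs = character(), path = NULL) {
    rec <- list(
        package = "nucleoFRAP",
        version = as.character(utils::packageVersion("nucleoFRAP")),
        config = config,
        inputs = if (length(inputs))
            as.list(tools::md5sum(inputs)) else list())
    if (!is.null(path)) {
        jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
        return(invisible(rec))
    }
    rec
}
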