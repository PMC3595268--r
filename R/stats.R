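#' @include AllClasses.R
NULL

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sample t-test with df = n_a + n_b - 2 and a
#' two-tailed p-value (the classic "Student's" test); Welch's
#' unequal-variance variant is available via \code{welch = TRUE}.
#'
#' @param a,b numeric samples, each with at least 2 finite values.
#' @param welch use the Welch (unequal-variance) variant.
#' @return a list: \code{t}, \code{p}, \code{df}, \code{mean_a},
#'   \code{mean_b}, \code{sd_a}, \code{sd_b}, \code{n_a}, \code{n_b}.
#' @examples
#' studentsT(c(4.3, 4.1, 4.6, 4.2), c(3.0, 3.2, 2.9, 3.1))
#' @export
studentsT <- function(a, b, welch = FALSE) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("each sample needs at least 2 finite values")
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
        stop("degenerate input: both samples constant and equal")
    ht <- stats::t.test(a, b, var.equal = !welch)
    list(t = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter),
         mean_a = mean(a), mean_b = mean(b),
         sd_a = stats::sd(a), sd_b = stats::sd(b),
         n_a = length(a), n_b = length(b))
}

#' Significance stars for a p-value
#'
#' \code{""} for p >= 0.05, \code{"*"} for p < 0.05, \code{"**"} for
#' p < 0.01, \code{"***"} for p < 0.001 (strict inequalities at every
#' boundary). Vectorized.
#'
#' @param p probability (or vector of probabilities) in [0, 1].
#' @return character vector of star annotations.
#' @examples
#' significanceStars(c(0.2, 0.04, 0.005, 0.0005))
#' @export
significanceStars <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p must be in [0, 1]")
    ifelse(p < 0.001, "***",
           ifelse(p < 0.01, "**",
                  ifelse(p < 0.05, "*", "")))
}

#' Summarize per-cell measurements by condition
#'
#' Per-condition mean, sample SD (denominator n - 1) and N, plus group
#' comparisons by pooled-variance two-tailed t-test with significance
#' stars. The unit of analysis is the cell, pooled across fields; no
#' multiple-testing correction is applied (each comparison is reported at
#' its nominal p-value).
#'
#' @param measurements data.frame of per-cell values.
#' @param value name of the measurement column.
#' @param group name of the condition column.
#' @param mode \code{"all-pairs"} or \code{"vs-control"}.
#' @param control control condition label (required for
#'   \code{"vs-control"}).
#' @param welch use Welch's t-test instead of pooled variance.
#' @return a list: \code{summary} (group, n, mean, sd) and
#'   \code{comparisons} (group_a, group_b, n_a, n_b, mean_a, mean_b, sd_a,
#'   sd_b, t_statistic, p_value, stars); comparisons is empty with a
#'   single condition.
#' @export
summarizeGroups <- function(measurements, value, group = "condition",
                            mode = c("all-pairs", "vs-control"),
                            control = NULL, welch = FALSE) {
    mode <- match.arg(mode)
    if (!value %in% names(measurements))
        stop("measurement column '", value, "' not found")
    if (!group %in% names(measurements))
        stop("condition column '", group, "' not found")
    v <- measurements[[value]]
    g <- as.character(measurements[[group]])
    keep <- is.finite(v)
    v <- v[keep]; g <- g[keep]
    groups <- unique(g)
    summary <- do.call(rbind, lapply(groups, function(gr) {
        x <- v[g == gr]
        data.frame(group = gr, n = length(x), mean = mean(x),
                   sd = stats::sd(x), stringsAsFactors = FALSE)
    }))
    pairs <- if (length(groups) < 2L) {
        matrix(character(0), ncol = 2L)
    } else if (mode == "all-pairs") {
        t(utils::combn(groups, 2L))
    } else {
        if (is.null(control) || !control %in% groups)
            stop("vs-control mode needs a control label present in the data")
        cbind(control, setdiff(groups, control))
    }
    comparisons <- if (nrow(pairs) == 0L) NULL
    else do.call(rbind, c(lapply(seq_len(nrow(pairs)), function(i) {
        tt <- studentsT(v[g == pairs[i, 1L]], v[g == pairs[i, 2L]],
                        welch = welch)
        data.frame(group_a = pairs[i, 1L], group_b = pairs[i, 2L],
                   n_a = tt$n_a, n_b = tt$n_b,
                   mean_a = tt$mean_a, mean_b = tt$mean_b,
                   sd_a = tt$sd_a, sd_b = tt$sd_b,
                   t_statistic = tt$t, p_value = tt$p,
                   stars = significanceStars(tt$p),
                   stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
    if (is.null(comparisons))
        comparisons <- data.frame(group_a = character(), group_b = character(),
                                  n_a = integer(), n_b = integer(),
                                  mean_a = numeric(), mean_b = numeric(),
                                  sd_a = numeric(), sd_b = numeric(),
                                  t_statistic = numeric(), p_value = numeric(),
                                  stars = character(), stringsAsFactors = FALSE)
    list(summary = summary, comparisons = comparisons)
}
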