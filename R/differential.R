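#' Per-peak condition/control signal ratios
#'
#' For each peak of a shared universe, the mean over condition samples of
#' (condition signal / control signal). Peaks with zero control signal are
#' excluded from the ratios and reported.
#'
#' @param condition numeric matrix (peaks x condition samples) of
#'   spike-in-normalized signals, rownames = peak ids; a single named
#'   vector is treated as one sample.
#' @param control named numeric vector of control signals on the same peak
#'   universe.
#' @return list with \code{ratios} (named numeric) and \code{excluded}
#'   (character, peaks dropped for zero control signal).
#' @export
perPeakRatio <- function(condition, control) {
    if (is.null(dim(condition)))
        condition <- matrix(condition, ncol = 1L,
                            dimnames = list(names(condition), "condition"))
    ids <- intersect(rownames(condition), names(control))
    if (length(ids) == 0L)
        stop("condition and control have disjoint peak universes")
    condition <- condition[ids, , drop = FALSE]
    control <- control[ids]
    excluded <- ids[control == 0]
    keep <- control > 0
    ratios <- rowMeans(condition[keep, , drop = FALSE] / control[keep])
    if (length(excluded))
        message(length(excluded), " peak(s) excluded for zero control signal")
    list(ratios = ratios, excluded = excluded)
}

#' Median split into two ordered groups
#'
#' Ids are sorted by value ascending (ties broken by id), the lower half
#' forms the first group and the upper half the second; for odd n the extra
#' element goes to the second (upper) group. With ratio inputs the first
#' group is the "most reduced" and the second the "least reduced".
#'
#' @param values named numeric vector (>= 2 elements).
#' @param labels names for the two groups, low first.
#' @return named list of two id vectors.
#' @examples
#' medianSplit(c(a = 0.1, b = 0.2, c = 0.8, d = 0.9),
#'             labels = c("most_reduced", "least_reduced"))
#' @export
medianSplit <- function(values, labels = c("most_reduced", "least_reduced")) {
    ids <- names(values)
    if (length(values) < 2L) stop("need at least 2 values to split")
    if (is.null(ids)) stop("values must be named by id")
    ord <- order(values, ids)
    n1 <- length(values) %/% 2L
    setNames(list(ids[ord[seq_len(n1)]],
                  ids[ord[(n1 + 1L):length(values)]]), labels)
}

#' Two-sample Student's t test
#'
#' Pooled-variance two-sample t with \code{df = n_x + n_y - 2} and a
#' two-tailed p value; \code{welch = TRUE} switches to the Welch variant
#' (via [stats::t.test()]). Degenerate inputs are defined rather than
#' errors: zero pooled variance with equal means gives t = 0, p = 1; zero
#' pooled variance with unequal means gives p = 0 as an underflow sentinel.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) variant.
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{method}.
#' @export
studentsT <- function(x, y, welch = FALSE) {
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least 2 observations")
    if (welch) {
        tt <- stats::t.test(x, y)
        return(list(statistic = unname(tt$statistic),
                    df = unname(tt$parameter),
                    p.value = tt$p.value, method = "welch"))
    }
    nx <- length(x); ny <- length(y)
    df <- nx + ny - 2L
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / df
    dm <- mean(x) - mean(y)
    if (sp2 == 0) {
        if (dm == 0)
            return(list(statistic = 0, df = df, p.value = 1,
                        method = "student"))
        return(list(statistic = sign(dm) * Inf, df = df, p.value = 0,
                    method = "student"))
    }
    t <- dm / sqrt(sp2 * (1 / nx + 1 / ny))
    list(statistic = t, df = df, p.value = 2 * pt(abs(t), df,
         lower.tail = FALSE), method = "student")
}

#' Percentage of peaks with increased signal
#'
#' Share (0--100) of peaks whose condition/reference ratio is strictly
#' greater than \code{threshold}; a ratio of exactly 1.0 counts as not
#' increased under the default.
#'
#' @param ratios numeric vector of per-peak ratios (non-empty).
#' @param threshold ratio cutoff, default 1.0.
#' @return percentage on the 0--100 scale.
#' @export
fractionIncreased <- function(ratios, threshold = 1.0) {
    if (length(ratios) == 0L) stop("empty peak universe")
    100 * mean(ratios > threshold)
}

#' Compare another mark's density between two peak groups
#'
#' Per-group summary statistics (n, mean, median, quartiles) of a signal
#' defined on the same ids (e.g. H3.3K27M density at the most- and
#' least-reduced H3K27me3 peaks), plus a two-sample Student's t test
#' between the groups.
#'
#' @param groups named list of two id vectors (e.g. from [medianSplit()]);
#'   each group must contain at least 2 ids with signal.
#' @param signal named numeric vector covering the grouped ids.
#' @param welch use the Welch t variant.
#' @return list with \code{summary} (data.frame, one row per group) and
#'   \code{test} (see [studentsT()]).
#' @export
groupDensityCompare <- function(groups, signal, welch = FALSE) {
    if (length(groups) != 2L || is.null(names(groups)))
        stop("groups must be a named list of two id vectors")
    vals <- lapply(groups, function(g) {
        miss <- setdiff(g, names(signal))
        if (length(miss))
            stop("signal missing for id(s): ", paste(utils::head(miss, 5),
                 collapse = ", "))
        signal[g]
    })
    if (any(lengths(vals) < 2L)) stop("each group needs at least 2 members")
    summ <- do.call(rbind, lapply(names(vals), function(g) {
        v <- vals[[g]]
        data.frame(group = g, n = length(v), mean = mean(v),
                   median = median(v), q1 = unname(quantile(v, 0.25)),
                   q3 = unname(quantile(v, 0.75)), stringsAsFactors = FALSE)
    }))
    list(summary = summ, test = studentsT(vals[[1L]], vals[[2L]],
                                          welch = welch))
}
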