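#' First-passage time statistics for one condition
#'
#' Mean and variance of the uncensored first-passage (target search) times
#' of an ensemble; replicates where the target was never reached within the
#' cell cycle are censored and reported separately, never averaged in.
#'
#' @param ensemble an ensemble data.frame (see \code{\link{runGrid}}) with
#'   columns \code{condition}, \code{first_passage}, \code{censored}.
#' @param condition condition label to select, or \code{NULL} for all rows.
#' @return list with \code{mean}, \code{variance}, \code{n} (uncensored
#'   count) and \code{nCensored}.
#' @export
firstPassageStats <- function(ensemble, condition = NULL) {
    df <- selectCondition(ensemble, condition)
    unc <- df[!df$censored, , drop = FALSE]
    if (nrow(unc) == 0L)
        stop("all replicates censored: no first-passage times to summarise")
    list(mean = mean(unc$first_passage),
         variance = if (nrow(unc) > 1L) stats::var(unc$first_passage)
                    else NA_real_,
         n = nrow(unc),
         nCensored = sum(df$censored))
}

#' Occupancy statistics for one condition
#'
#' Moments of the target-site occupancy fraction.  Two censoring protocols
#' exist and must be chosen explicitly: the mobile-obstacle protocol keeps
#' censored replicates as zeros (the site simply was never occupied within
#' the cell cycle), while the immobile-obstacle protocol discards them
#' (runs where the target site is never reached are excluded from the
#' occupancy average).
#'
#' @inheritParams firstPassageStats
#' @param discardCensored \code{TRUE} for the immobile protocol.
#' @return list with \code{mean}, \code{variance}, \code{n}.
#' @export
occupancyStats <- function(ensemble, condition = NULL,
                           discardCensored = FALSE) {
    df <- selectCondition(ensemble, condition)
    if (discardCensored) df <- df[!df$censored, , drop = FALSE]
    if (nrow(df) == 0L)
        stop("no replicates left after discarding censored runs")
    occ <- df$occupancy_fraction
    occ[df$censored] <- 0
    list(mean = mean(occ),
         variance = if (length(occ) > 1L) stats::var(occ) else NA_real_,
         n = length(occ))
}

#' Probability of reaching the target within the cell cycle
#'
#' @inheritParams firstPassageStats
#' @return fraction of uncensored replicates, in [0, 1].
#' @export
reachProbability <- function(ensemble, condition = NULL) {
    df <- selectCondition(ensemble, condition)
    if (nrow(df) == 0L) stop("empty ensemble")
    mean(!df$censored)
}

#' Pearson correlation between crowding and a condition-level statistic
#'
#' @param crowding condition-level crowding fractions (covered DNA).
#' @param values condition-level means (e.g. mean search time or mean
#'   occupancy), same length.
#' @return Pearson product-moment correlation coefficient.
#' @examples
#' crowdingCorrelation(c(0, 0.09, 0.26), c(27, 36, 36.5))
#' @export
crowdingCorrelation <- function(crowding, values) {
    if (length(crowding) != length(values))
        stop("crowding and values must have equal length")
    if (length(crowding) < 3L)
        stop("need at least 3 conditions for a correlation")
    if (stats::sd(crowding) == 0 || stats::sd(values) == 0)
        stop("constant input: correlation undefined")
    stats::cor(crowding, values)
}

#' One-way ANOVA with Tukey's range test
#'
#' Tests whether first-passage samples differ across conditions: a one-way
#' ANOVA F test followed by Tukey's honest significant difference test for
#' all pairwise comparisons at the given confidence level.  No further
#' multiple-testing correction is layered on top.
#'
#' @param groups named list of numeric vectors (uncensored first-passage
#'   samples per condition), at least two groups of at least two values.
#' @param alpha significance level for the pairwise flags (default 0.05,
#'   i.e. 95\% family-wise confidence).
#' @return list with \code{F}, \code{p}, \code{tukey} (a data.frame with
#'   columns \code{comparison}, \code{diff}, \code{lwr}, \code{upr},
#'   \code{pAdj}, \code{significant}) and \code{alpha}.
#' @examples
#' anovaTukey(list(a = rnorm(10), b = rnorm(10, 5), c = rnorm(10)))
#' @export
anovaTukey <- function(groups, alpha = 0.05) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("need at least two groups")
    sizes <- vapply(groups, length, 1L)
    if (any(sizes < 2L))
        stop("each group needs at least two uncensored values")
    if (is.null(names(groups)))
        names(groups) <- paste0("g", seq_along(groups))
    df <- data.frame(
        value = unlist(groups, use.names = FALSE),
        group = factor(rep(names(groups), sizes), levels = names(groups)))
    fit <- stats::aov(value ~ group, data = df)
    tab <- summary(fit)[[1]]
    hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    tukey <- data.frame(
        comparison = rownames(hsd),
        diff = hsd[, "diff"], lwr = hsd[, "lwr"], upr = hsd[, "upr"],
        pAdj = hsd[, "p adj"],
        significant = hsd[, "p adj"] < alpha,
        row.names = NULL, stringsAsFactors = FALSE)
    list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"], tukey = tukey,
         alpha = alpha)
}

#' Notched-boxplot summary of a sample
#'
#' Computes the six-part boxplot description used for the search-time and
#' occupancy figures: median, quartiles (linear interpolation of order
#' statistics, the common type-7 convention), the interquartile range, a
#' lower whisker at \code{max(Q1 - 1.5 IQR, min(x))}, an upper whisker at
#' \code{min(Q3 + 1.5 IQR, max(x))}, the outliers beyond the whisker span,
#' and median notches at \code{median +/- 1.57 IQR / sqrt(n)} (the standard
#' convention for approximate 95\% confidence intervals on the median:
#' non-overlapping notches indicate medians that differ at the 5\% level).
#'
#' @param x numeric sample, n >= 1.
#' @return list with \code{median}, \code{q1}, \code{q3}, \code{iqr},
#'   \code{lowerWhisker}, \code{upperWhisker}, \code{outliers},
#'   \code{notchLow}, \code{notchHigh}, \code{n}.
#' @examples
#' boxplotSummary(1:7)
#' @export
boxplotSummary <- function(x) {
    x <- as.numeric(x)
    if (length(x) < 1L || any(!is.finite(x))) stop("need a finite sample")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lw <- max(q[1] - 1.5 * iqr, min(x))
    uw <- min(q[3] + 1.5 * iqr, max(x))
    half <- 1.57 * iqr / sqrt(length(x))
    list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         lowerWhisker = lw, upperWhisker = uw,
         outliers = x[x < lw | x > uw],
         notchLow = q[2] - half, notchHigh = q[2] + half,
         n = length(x))
}

selectCondition <- function(ensemble, condition) {
    required <- c("condition", "first_passage", "censored",
                  "occupancy_fraction")
    missing <- setdiff(required, names(ensemble))
    if (length(missing))
        stop("ensemble is missing columns: ", paste(missing, collapse = ", "))
    if (is.null(condition)) return(ensemble)
    ensemble[ensemble$condition %in% condition, , drop = FALSE]
}
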