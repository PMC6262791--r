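# The statistical layer used alongside the image measurements: unpaired
# two-sample t tests (Student and Welch), the F test on variances, Fisher's
# exact test on 2x2 contingency tables, type-7 box-plot summaries, and the
# simple fraction/penetrance arithmetic. Test machinery is delegated to the
# standard implementations in base R's stats; this module fixes the
# conventions (two-sided p values, hinge definitions, rounding) and the
# degenerate-input behavior.

#' Unpaired two-sample t test
#'
#' Student's pooled-variance t (df = n_a + n_b - 2) when
#' `equal_variance = TRUE`, otherwise Welch's t with Welch-Satterthwaite
#' degrees of freedom (the variant used when group variances differ).
#' Always two-sided.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param equal_variance pool the variances?
#' @return list `t`, `df`, `p`, and `flagged` (TRUE with `t = NA` when
#'   both groups have zero variance, where t is undefined).
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6), equal_variance = TRUE)
#' @export
two_sample_t <- function(a, b, equal_variance = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = NA_real_, df = NA_real_, p = NA_real_, flagged = TRUE))
    # distinct constants: infinite evidence of a difference
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0, flagged = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = equal_variance)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, flagged = FALSE)
}

#' F test for equality of two variances
#'
#' `F = var(a) / var(b)` against the F distribution with
#' `(n_a - 1, n_b - 1)` degrees of freedom; two-sided
#' `p = 2 * min(P(F <= f), P(F >= f))`, capped at 1. Used to compare the
#' spread (not the mean) of orientation-angle distributions.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list `F`, `df` (length-2), `p`, `flagged` (TRUE with `F = Inf`
#'   or `NA` when the denominator variance is 0).
#' @export
f_variance_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(b) == 0) {
    f <- if (stats::var(a) == 0) NA_real_ else Inf
    return(list(F = f, df = c(length(a) - 1L, length(b) - 1L),
                p = if (is.na(f)) NA_real_ else 0, flagged = TRUE))
  }
  ht <- stats::var.test(a, b)
  list(F = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       flagged = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p value by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of nonnegative integer counts (e.g. final
#'   position stalk/cup by donor condition).
#' @return list `p`, `flagged` (TRUE with `p = 1` when a margin is zero,
#'   where the table carries no information).
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (sum(table) == 0L) stop("empty table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, flagged = TRUE))
  list(p = stats::fisher.test(table)$p.value, flagged = FALSE)
}

#' Box-and-whisker summary (type-7 hinges)
#'
#' The box-plot convention used for the figure summaries: the band is the
#' median, the hinges are the first and third quartiles computed by type-7
#' linear interpolation (the default of ggplot2), whiskers extend from the
#' hinges to the most extreme data values within 1.5 * IQR, and points
#' beyond the whiskers are outliers. Whiskers are always attained data
#' values, never interpolated bounds.
#'
#' @param values numeric vector, length >= 1.
#' @return list `median`, `lower_hinge`, `upper_hinge`, `lower_whisker`,
#'   `upper_whisker`, `outliers`.
#' @examples
#' boxplot_summary(c(1, 2, 3, 4, 100))
#' @export
boxplot_summary <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  inside <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  list(median = q[2], lower_hinge = q[1], upper_hinge = q[3],
       lower_whisker = min(values[inside]), upper_whisker = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Percentage of scored cells in a contingency row
#'
#' `100 * in_stalk / total_scored`, reported to one decimal with
#' conventional (half-up) rounding -- the form in which transplant
#' contributions are quoted (e.g. 32 of 41 cells = 78.0%).
#'
#' @param in_stalk count contributing to the outcome of interest.
#' @param total_scored total cells scored (> 0).
#' @return percentage to one decimal.
#' @examples
#' contingency_fraction(10, 23)  # 43.5
#' @export
contingency_fraction <- function(in_stalk, total_scored) {
  if (total_scored <= 0) stop("`total_scored` must be > 0")
  if (in_stalk < 0 || in_stalk > total_scored)
    stop("`in_stalk` must lie in [0, total_scored]")
  pct <- 100 * in_stalk / total_scored
  floor(pct * 10 + 0.5) / 10
}

#' Normalize phenotype penetrance to a control group
#'
#' Expresses a treated group's phenotype percentage relative to its
#' vehicle control: `100 * treated_pct / control_pct`. 100 means no
#' change; below 100, rescue; above 100, exacerbation.
#'
#' @param treated_pct treated-group percentage.
#' @param control_pct control-group percentage (> 0).
#' @return normalized percentage.
#' @export
normalize_penetrance <- function(treated_pct, control_pct) {
  if (control_pct <= 0) stop("`control_pct` must be > 0")
  if (treated_pct < 0) stop("`treated_pct` must be >= 0")
  100 * treated_pct / control_pct
}
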