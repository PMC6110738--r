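#' Two-sided Fisher exact p for a 2x2 table
#'
#' Sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (with a 1e-7 relative slack against floating-point ties, the common
#' convention).
#'
#' @param a,b,c,d cell counts: rows are groups, columns feature
#'   present/absent.
#' @return p-value in [0, 1].
#' @keywords internal
fisherExactP <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0L, k - n)
  hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Yates-corrected chi-squared for a 2x2 table
#'
#' Pearson chi-squared with continuity correction, 1 df; the correction
#' term |O-E| - 1/2 clamps at zero so equal proportions give statistic 0.
#'
#' @inheritParams fisherExactP
#' @return list with `statistic` and `p`.
#' @keywords internal
yatesChisq <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
  list(statistic = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

.expectedCounts <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  outer(rowSums(O), colSums(O)) / sum(O)
}

#' 2x2 association test with an expected-count chooser
#'
#' The group-comparison workhorse: given a 2x2 table (feature
#' present/absent in two sample groups) the test is chosen from the
#' theoretical (expected) cell counts — if any expected count falls below
#' `thresholds$expected_count_min` (default 5) a two-sided Fisher exact
#' test is used, otherwise a Yates continuity-corrected chi-squared with
#' 1 df. `force` overrides the chooser.
#'
#' @param a,b count of samples with/without the feature in group 1.
#' @param c,d count of samples with/without the feature in group 2.
#' @param thresholds list from [ergThresholds()].
#' @param force `NA` (chooser), `"fisher_exact"` or `"chi2_yates"`.
#' @return list with `statistic` (NA for Fisher), `p`, `test_used`.
#' @examples
#' assocTest(3, 198, 7, 289)   # sparse table -> Fisher
#' assocTest(19, 182, 25, 271) # -> Yates chi-squared
#' @export
assocTest <- function(a, b, c, d, thresholds = ergThresholds(), force = NA) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("degenerate table")
  use <- if (!is.na(force)) {
    match.arg(force, c("fisher_exact", "chi2_yates"))
  } else if (min(.expectedCounts(a, b, c, d)) < thresholds$expected_count_min) {
    "fisher_exact"
  } else {
    "chi2_yates"
  }
  if (use == "fisher_exact") {
    list(statistic = NA_real_, p = fisherExactP(a, b, c, d),
         test_used = "fisher_exact")
  } else {
    y <- yatesChisq(a, b, c, d)
    list(statistic = y$statistic, p = y$p, test_used = "chi2_yates")
  }
}

#' Welch unequal-variance t-test
#'
#' Thin wrapper over [stats::t.test()] with the conventions used here:
#' a two-sided default, a `"greater"` alternative for the
#' higher-mean-in-x question, and p = 1 by convention when both groups
#' are constant with equal means.
#'
#' @param x,y numeric vectors, each of length >= 2, finite.
#' @param tail `"two"` or `"greater"` (mean of `x` greater).
#' @return list with `statistic`, `p`, `test_used = "t_test"`.
#' @export
welchT <- function(x, y, tail = c("two", "greater")) {
  tail <- match.arg(tail)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("non-finite values in input")
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, p = 1, test_used = "t_test"))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p = 0,
                test_used = "t_test"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE,
                      alternative = if (tail == "two") "two.sided" else "greater")
  list(statistic = unname(tt$statistic), p = tt$p.value, test_used = "t_test")
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and `p`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared (1 df) via [survival::survdiff()];
#' invariant under swapping the group labels.
#'
#' @param times1,times2 positive follow-up times per group.
#' @param events1,events2 logical event indicators per group.
#' @return list with `statistic`, `p`, `test_used = "logrank"`, and the
#'   per-group observed event counts `obs`.
#' @export
logrankTest <- function(times1, events1, times2, events2) {
  if (any(c(times1, times2) <= 0)) stop("times must be positive")
  events1 <- as.logical(events1); events2 <- as.logical(events2)
  if (!any(events1) && !any(events2)) stop("no events")
  time <- c(times1, times2)
  event <- c(events1, events2)
  grp <- rep(1:2, c(length(times1), length(times2)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- sd$chisq
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       test_used = "logrank",
       obs = unname(sd$obs))
}

#' Percentage of a stratum satisfying a predicate
#'
#' @param cohort an `ErgCohort` or a clinical data.frame.
#' @param predicate logical vector over clinical rows (or a function of
#'   the clinical table returning one).
#' @param stratum logical vector over clinical rows (or such a function)
#'   defining the denominator; must select at least one sample.
#' @return percentage (0-100).
#' @examples
#' ## proportion of fusion-positive samples among Caucasian patients
#' cl <- table1Cohort()
#' groupProportion(cl, clinical(cl)$group == "ERG_POS",
#'                 clinical(cl)$ancestry == "CA")
#' @export
groupProportion <- function(cohort, predicate, stratum) {
  cl <- if (is(cohort, "ErgCohort")) clinical(cohort) else cohort
  if (is.function(predicate)) predicate <- predicate(cl)
  if (is.function(stratum)) stratum <- stratum(cl)
  stopifnot(is.logical(predicate), is.logical(stratum),
            length(predicate) == nrow(cl), length(stratum) == nrow(cl))
  n <- sum(stratum)
  if (n == 0L) stop("empty stratum")
  100 * sum(predicate & stratum) / n
}
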