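# Cohort statistics: contingency tests, two-sample t test, Kaplan-Meier
# estimation and the log-rank comparison. These wrap the standard
# stats/survival implementations behind the contracts the pipeline relies
# on (no continuity correction, pooled-variance t, explicit degenerate-input
# errors).

#' Pearson chi-squared test of independence
#'
#' `sum((O - E)^2 / E)` with expected counts from the margins, no continuity
#' correction, df = (r-1)(c-1), upper-tail p-value.
#'
#' @param counts r x c matrix of nonnegative integer counts.
#' @return list with `statistic`, `df`, `p`.
#' @examples
#' # 3 x 2 contingency of immune infiltration (no-low / moderate-high)
#' pearsonChi2(rbind(c(166, 80), c(13, 19), c(18, 11)))$p  # 0.011
#' @export
pearsonChi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: every row and column must have positive total")
  # the asymptotic p-value is returned regardless of expected-count size;
  # contingencyTest() is the place where sparse 2x2 tables fall back to Fisher
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by the point-probability rule: the sum over all tables
#' with the observed margins whose hypergeometric probability does not
#' exceed the observed table's.
#'
#' @param counts 2 x 2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(rbind(c(4, 242), c(3, 29)))  # 0.035
#' @export
fisherExact2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("only 2 x 2 tables are supported")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: every row and column must have positive total")
  unname(stats::fisher.test(counts)$p.value)
}

#' Pick chi-squared or Fisher for a contingency table
#'
#' Chi-squared by default; Fisher's exact test when the table is 2 x 2 and
#' any expected cell count is below 5.
#'
#' @param counts r x c count matrix.
#' @return list with `test` ("chi2" or "fisher"), `p`, and for chi-squared
#'   also `statistic` and `df`.
#' @export
contingencyTest <- function(counts) {
  counts <- as.matrix(counts)
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(dim(counts) == c(2L, 2L)) && any(E < 5)) {
    list(test = "fisher", p = fisherExact2x2(counts))
  } else {
    c(list(test = "chi2"), pearsonChi2(counts))
  }
}

#' Two-sample Student t test (pooled variance)
#'
#' Two-sided pooled-variance t test. With zero pooled variance, equal means
#' give `statistic = 0, p = 1`; unequal means are flagged as an error.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list with `statistic`, `df`, `p`.
#' @export
studentT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = length(x) + length(y) - 2, p = 1))
    stop("zero pooled variance with unequal means: t is undefined")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Kaplan-Meier product-limit estimator
#'
#' Right-continuous step estimate of the survival function, with S(0) = 1.
#' Wraps [survival::survfit()].
#'
#' @param time positive event/censoring times (months).
#' @param event 0/1 event indicators.
#' @return list with `time`, `surv` (the step function values just after
#'   each observed event time), `n_risk`, `n_event`, and `fit` (the
#'   underlying `survfit` object).
#' @export
kmEstimator <- function(time, event) {
  if (length(time) < 1L) stop("at least one subject is required")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, fit = fit)
}

#' Evaluate a Kaplan-Meier estimate at given times
#' @param km result of [kmEstimator()].
#' @param t times at which to evaluate S(t).
#' @return numeric vector of survival probabilities.
#' @export
kmSurvival <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test between survival groups
#'
#' Observed-minus-expected chi-squared statistic with df = groups - 1.
#' Wraps [survival::survdiff()]; requires at least one event.
#'
#' @param time positive times.
#' @param event 0/1 event indicators.
#' @param group group label per subject (>= 2 groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
  if (length(unique(group)) < 2L) stop("log-rank needs at least two groups")
  if (sum(event) < 1L)
    stop("log-rank is undefined with zero events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}
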