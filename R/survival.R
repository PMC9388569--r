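# Cohort statistics: Wilcoxon rank-sum and Fisher's exact comparisons,
# Kaplan-Meier product-limit estimation and the two-group log-rank test,
# plus expression dichotomization and the combined low/low group. The
# survival machinery is implemented from first principles (product-limit,
# O/E/V log-rank) so each term is directly checkable against hand
# tabulation; the survival package serves as an independent cross-check in
# the test suite, never as the implementation.

#' Wilcoxon rank-sum test
#'
#' Midranks with tie correction; the exact distribution is enumerated when
#' the pooled sample size is at most 20 and there are no ties, otherwise
#' the normal approximation with continuity correction is used.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `statistic` (rank-sum W for `x`) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 20L
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric test; the two-sided p sums the probabilities
#' of all tables (with the margins fixed) whose probability does not exceed
#' the observed table's. The odds ratio is the sample odds ratio
#' `(a*d)/(b*c)`, `Inf` when `b*c = 0` (and `NaN` when both products
#' vanish).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stopf("need a 2x2 table")
  if (any(tab < 0)) stopf("cell counts must be non-negative")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c_ + d; n1 <- a + c_
  odds_ratio <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  if (m1 == 0 || m2 == 0 || n1 == 0 || b + d == 0)
    return(list(odds_ratio = odds_ratio, p = 1))
  k <- max(0, n1 - m2):min(n1, m1)
  probs <- stats::dhyper(k, m1, m2, n1)
  p_obs <- stats::dhyper(a, m1, m2, n1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = odds_ratio, p = min(1, p))
}

#' Kaplan-Meier product-limit estimator
#'
#' Right-censored records leave the risk set without an event; `S(0) = 1`
#' and the estimate is a non-increasing step function. The median survival
#' is the smallest time with `S(t) <= 0.5` (`NA` when the curve never
#' crosses 0.5).
#'
#' @param time positive event/censoring times.
#' @param event logical, `TRUE` when the event (death) was observed.
#' @return data frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (one row per distinct time), with the median survival in
#'   `attr(, "median")`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stopf("need at least one record")
  if (any(time <= 0)) stopf("survival times must be positive")
  event <- as.logical(event)
  times <- sort(unique(time))
  n <- length(time)
  surv <- 1
  rows <- lapply(times, function(t) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event)
    cns <- sum(time == t & !event)
    if (d > 0) surv <<- surv * (1 - d / at_risk)
    data.frame(time = t, n_risk = at_risk, n_event = d, n_censor = cns,
               surv = surv)
  })
  out <- do.call(rbind, rows)
  med <- out$time[out$surv <= 0.5][1]
  attr(out, "median") <- if (is.na(med)) NA_real_ else med
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in group A are compared
#' with their hypergeometric expectation given the risk sets;
#' the statistic is `(sum O - sum E)^2 / sum V` with the usual
#' hypergeometric variance term `n1*n2*d*(n-d) / (n^2*(n-1))`, referred to
#' chi-squared with 1 df. Symmetric in group exchange.
#'
#' @param time_a,event_a times and event indicators of group A.
#' @param time_b,event_b times and event indicators of group B.
#' @return list with `statistic`, `p`, `observed` and `expected` events in
#'   group A.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    stopf("both groups must be non-empty")
  if (any(c(time_a, time_b) <= 0)) stopf("survival times must be positive")
  event_a <- as.logical(event_a); event_b <- as.logical(event_b)
  if (sum(event_a) + sum(event_b) == 0L)
    stopf("log-rank test undefined with zero events")
  event_times <- sort(unique(c(time_a[event_a], time_b[event_b])))
  O <- E <- V <- 0
  for (t in event_times) {
    n1 <- sum(time_a >= t); n2 <- sum(time_b >= t)
    ntot <- n1 + n2
    d <- sum(time_a == t & event_a) + sum(time_b == t & event_b)
    o1 <- sum(time_a == t & event_a)
    O <- O + o1
    E <- E + d * n1 / ntot
    if (ntot > 1L)
      V <- V + d * (n1 / ntot) * (n2 / ntot) * (ntot - d) / (ntot - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Dichotomize expression into low and high groups
#'
#' `low` means strictly below the cutoff; a value equal to the cutoff is
#' `high`. In `mean` mode the cutoff is the cohort mean of the values.
#'
#' @param values named per-case log2 expression values (at least 2).
#' @param cutoff_mode `"mean"` or `"fixed"`.
#' @param fixed_cutoff cutoff used in `fixed` mode.
#' @return list with `cutoff` and `labels` (named character vector,
#'   `"low"`/`"high"`).
#' @export
dichotomize_expression <- function(values, cutoff_mode = c("mean", "fixed"),
                                   fixed_cutoff = NULL) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (length(values) < 2L) stopf("need at least 2 cases")
  cutoff <- if (cutoff_mode == "mean") mean(values) else {
    if (is.null(fixed_cutoff)) stopf("fixed cutoff_mode needs fixed_cutoff")
    fixed_cutoff
  }
  labels <- ifelse(values < cutoff, "low", "high")
  list(cutoff = cutoff, labels = stats::setNames(labels, names(values)))
}

#' Combined low/low expression group over two genes
#'
#' @param labels_a,labels_b named `"low"`/`"high"` label vectors from
#'   [dichotomize_expression()] over matched case sets.
#' @return named character vector, `"low/low"` for cases low in both genes
#'   and `"other"` otherwise.
#' @export
combined_low_group <- function(labels_a, labels_b) {
  only_a <- setdiff(names(labels_a), names(labels_b))
  only_b <- setdiff(names(labels_b), names(labels_a))
  if (length(only_a) || length(only_b))
    stopf("case sets differ%s%s",
          if (length(only_a)) paste0("; only in first: ",
                                     paste(utils::head(only_a, 5),
                                           collapse = ", ")) else "",
          if (length(only_b)) paste0("; only in second: ",
                                     paste(utils::head(only_b, 5),
                                           collapse = ", ")) else "")
  if (length(labels_a) == 0L) stopf("case sets are empty")
  lab <- ifelse(labels_a == "low" & labels_b[names(labels_a)] == "low",
                "low/low", "other")
  stats::setNames(lab, names(labels_a))
}

#' Expression-stratified survival comparison
#'
#' Convenience wrapper: dichotomizes expression, runs the log-rank test
#' between the low and high groups and reports group sizes and median
#' survival.
#'
#' @param values named per-case expression values.
#' @param time,event named (or matched-order) survival data for the same
#'   cases.
#' @param cutoff_mode,fixed_cutoff passed to [dichotomize_expression()].
#' @return one-row data frame: cutoff, group sizes, log-rank statistic and
#'   p, median survival per group.
#' @export
survival_by_expression <- function(values, time, event,
                                   cutoff_mode = c("mean", "fixed"),
                                   fixed_cutoff = NULL) {
  grp <- dichotomize_expression(values, cutoff_mode, fixed_cutoff)
  low <- grp$labels == "low"
  if (!any(low) || all(low))
    stopf("expression cutoff %g leaves an empty group", grp$cutoff)
  lr <- logrank_test(time[low], event[low], time[!low], event[!low])
  med_l <- attr(km_estimate(time[low], event[low]), "median")
  med_h <- attr(km_estimate(time[!low], event[!low]), "median")
  data.frame(cutoff = grp$cutoff, n_low = sum(low), n_high = sum(!low),
             statistic = lr$statistic, p = lr$p,
             median_low = med_l, median_high = med_h)
}
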