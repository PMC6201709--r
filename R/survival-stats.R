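# Survival-analysis primitives used throughout the pipeline: univariate
# Cox proportional-hazards fits (score test), the two-group log-rank test,
# Harrell's concordance index, the Kaplan-Meier estimator and BH FDR.
# Model fitting is delegated to the survival package (Breslow tie handling);
# the concordance index is computed by explicit pair counting so that the
# comparability rule (the smaller time must be an event; tied event times
# are not comparable) is under the package's control.

#' Univariate Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ x` by partial likelihood with Breslow tie
#' handling and reports the score test, whose statistic for a dichotomous
#' covariate coincides with the log-rank chi-square in the absence of tied
#' event times.
#'
#' @param x Numeric covariate, one value per sample.
#' @param time Follow-up times (days).
#' @param event Event indicators (1 = event, 0 = censored).
#' @return List of class `CoxFitResult`: `coefficient` (log hazard ratio),
#'   `score_statistic`, `p_value` (score test), `n_events`, `converged`.
#' @examples
#' cox_univariate(c(1, 1, 0, 0), c(2, 3, 8, 9), c(1, 1, 1, 0))
#' @export
cox_univariate <- function(x, time, event) {
  if (length(x) != length(time) || length(time) != length(event)) {
    stopf("x, time and event must have equal length")
  }
  n_events <- sum(event == 1)
  if (n_events < 1) stopf("at least one event is required")
  out <- list(coefficient = 0, score_statistic = 0, p_value = 1,
              n_events = n_events, converged = TRUE)
  class(out) <- "CoxFitResult"
  if (stats::var(x) == 0) {
    # no variation: zero score statistic, nothing to estimate
    return(out)
  }
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ x,
      ties = "breslow",
      control = survival::coxph.control(eps = 1e-8, iter.max = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(stats::coef(fit))) {
    warnf("Cox fit failed to converge; reporting p = 1")
    out$converged <- FALSE
    return(out)
  }
  sct <- summary(fit)$sctest
  out$coefficient <- unname(stats::coef(fit))
  out$score_statistic <- unname(sct["test"])
  out$p_value <- unname(sct["pvalue"])
  if (fit$iter >= 50) {
    warnf("Cox fit hit the iteration cap; coefficient may be unstable")
    out$converged <- FALSE
  }
  out
}

#' Cox score test for many features at once
#'
#' The score test of a univariate Cox model is evaluated at beta = 0, so it
#' needs no iterative fitting: with Breslow tie handling the statistic is
#' U^2 / V with U the sum over event times of the observed minus risk-set
#' mean covariate and V the corresponding risk-set variance. This matches
#' the `p_value` of [cox_univariate()] and computes all rows of a feature
#' matrix in one pass.
#'
#' @param vals Numeric matrix, features x samples.
#' @inheritParams cox_univariate
#' @return Data frame with one row per feature: `score_statistic`,
#'   `p_value`.
#' @export
cox_score_test_matrix <- function(vals, time, event) {
  n <- length(time)
  if (ncol(vals) != n || length(event) != n) {
    stopf("vals columns, time and event must agree in length")
  }
  ord <- order(time, decreasing = TRUE)
  vo <- vals[, ord, drop = FALSE]
  to <- time[ord]
  # cumulative risk-set sums: column k holds sums over the k largest times
  cs1 <- t(apply(vo, 1, cumsum))
  cs2 <- t(apply(vo^2, 1, cumsum))
  ev_times <- sort(unique(time[event == 1]))
  U <- numeric(nrow(vals))
  V <- numeric(nrow(vals))
  for (t_ev in ev_times) {
    at_risk <- sum(to >= t_ev)             # descending order prefix
    deaths <- which(time == t_ev & event == 1)
    d <- length(deaths)
    s1 <- cs1[, at_risk] / at_risk
    s2 <- cs2[, at_risk] / at_risk
    x_d <- if (d == 1) vals[, deaths] else rowSums(vals[, deaths,
                                                        drop = FALSE])
    U <- U + x_d - d * s1
    V <- V + d * (s2 - s1^2)
  }
  chisq <- ifelse(V > 1e-12, U^2 / V, 0)
  data.frame(score_statistic = chisq,
             p_value = ifelse(V > 1e-12,
                              stats::pchisq(chisq, 1, lower.tail = FALSE),
                              1),
             row.names = rownames(vals))
}

#' Two-group log-rank test
#'
#' Standard Mantel-Haenszel log-rank chi-square with one degree of freedom.
#'
#' @param labels Group membership, a vector with exactly two distinct,
#'   non-empty levels (any type).
#' @inheritParams cox_univariate
#' @return List of class `LogRankResult`: `chi_square`, `p_value`,
#'   `group_sizes` (named integer vector).
#' @export
logrank_two_group <- function(labels, time, event) {
  if (length(labels) != length(time) || length(time) != length(event)) {
    stopf("labels, time and event must have equal length")
  }
  g <- factor(labels)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stopf("exactly two non-empty groups are required (got %d)", nlevels(g))
  }
  sizes <- table(g)
  if (sum(event == 1) == 0) {
    warnf("no events observed; log-rank test carries no information")
    chisq <- 0
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    chisq <- sd$chisq
    if (!is.finite(chisq)) chisq <- 0
  }
  out <- list(chi_square = chisq,
              p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
              group_sizes = stats::setNames(as.integer(sizes), names(sizes)))
  class(out) <- "LogRankResult"
  out
}

#' Harrell's concordance index
#'
#' Fraction of comparable sample pairs whose risk ordering agrees with their
#' survival ordering. A pair is comparable iff the strictly smaller time
#' carries an event; pairs with tied times are not comparable. Tied risk
#' scores contribute 0.5. The standard error is a leave-one-out jackknife
#' over samples.
#'
#' @param risk_score Numeric risk scores (higher = worse prognosis).
#' @inheritParams cox_univariate
#' @return List of class `ConcordanceResult`: `c_index`,
#'   `comparable_pairs`, `concordant` (tied scores counted 0.5), `se`.
#' @export
concordance_index <- function(risk_score, time, event) {
  n <- length(risk_score)
  if (length(time) != n || length(event) != n) {
    stopf("risk_score, time and event must have equal length")
  }
  # comparable[i, j]: time[i] < time[j] strictly and subject i had the event
  comp <- outer(time, time, `<`) & (event == 1)
  # pair credit: 1 if the earlier-event subject has the higher risk, 0.5 ties
  credit <- outer(risk_score, risk_score, `>`) +
    0.5 * outer(risk_score, risk_score, `==`)
  comparable <- sum(comp)
  if (comparable == 0) stopf("no comparable pairs (all censored or tied)")
  concordant <- sum(credit[comp])
  cidx <- concordant / comparable
  # jackknife se: pair (i, j) involves both subjects, so removing subject i
  # removes row i and column i of the comparable-pair matrix
  conc_mat <- credit * comp
  drop_comp <- rowSums(comp) + colSums(comp)
  drop_conc <- rowSums(conc_mat) + colSums(conc_mat)
  keep <- (comparable - drop_comp) > 0
  if (sum(keep) >= 2) {
    loo <- (concordant - drop_conc[keep]) / (comparable - drop_comp[keep])
    m <- length(loo)
    se <- sqrt((m - 1) / m * sum((loo - mean(loo))^2))
  } else {
    se <- NA_real_
  }
  out <- list(c_index = cidx, comparable_pairs = comparable,
              concordant = concordant, se = se)
  class(out) <- "ConcordanceResult"
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, returned as a step-
#' function table suitable for plotting or numerical integration.
#'
#' @inheritParams cox_univariate
#' @return Data frame with columns `time`, `n_risk`, `n_event`, `survival`,
#'   one row per distinct observed time.
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1) stopf("at least one sample is required")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

# restricted mean survival time: area under the KM curve up to `tau`
# (default: the largest observed time). Used to order groups by prognosis.
restricted_mean_survival <- function(time, event, tau = max(time)) {
  km <- km_curve(time, event)
  km <- km[km$time <= tau, , drop = FALSE]
  times <- c(0, km$time, tau)
  surv <- c(1, km$survival, if (nrow(km)) km$survival[nrow(km)] else 1)
  sum(utils::head(surv, -1) * diff(times))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, as in
#' `p.adjust(method = "BH")`, with input validation.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
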