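#' @title Validation metrics
#' @description Confusion statistics, rank-based ROC AUC with bootstrap
#'   confidence intervals and a paired bootstrap AUC-difference test,
#'   Kaplan-Meier estimation with the log-rank test, mortality rates per
#'   100 patient-years, and the nine-variable logistic comparator with
#'   Hosmer-Lemeshow calibration.
#' @name evaluation
NULL

#' Confusion metrics of a binary prediction
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), diagnostic accuracy
#' = (TP+TN)/n, with "positive" meaning the event (poor survival).
#'
#' @param predicted 0/1 predictions.
#' @param truth 0/1 truth.
#' @return List with `sensitivity`, `specificity`, `accuracy`, the 2x2
#'   counts (`tp`, `fp`, `tn`, `fn`) and a `degenerate` flag set when the
#'   truth contains a single class (the undefined rate is `NA`).
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0) {
    stop("predicted and truth must be aligned and non-empty", call. = FALSE)
  }
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("predicted and truth must be coded {0, 1}", call. = FALSE)
  }
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(truth),
    tp = tp, fp = fp, tn = tn, fn = fn,
    degenerate = (tp + fn == 0) || (tn + fp == 0)
  )
}

#' ROC area under the curve (rank formulation)
#'
#' Mann-Whitney AUC with half-credit for ties: the probability that a
#' randomly chosen event case outranks a randomly chosen non-event case.
#' The orientation is explicit: with `higher_predicts_event = TRUE`
#' (default) larger scores are taken to predict the event; set it to
#' `FALSE` for scores (like the DIFE) where smaller values predict the
#' event. The orientation is never flipped automatically.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 event labels; both classes must be present.
#' @param higher_predicts_event Score orientation.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, higher_predicts_event = TRUE) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must be aligned", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop("labels must contain both classes coded {0, 1}", call. = FALSE)
  }
  s <- if (higher_predicts_event) scores else -scores
  r <- rank(s, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified resample of case/control indices.
stratified_resample <- function(labels) {
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  c(sample(i1, length(i1), replace = TRUE),
    sample(i0, length(i0), replace = TRUE))
}

#' Bootstrap confidence interval for the ROC AUC
#'
#' Stratified case resampling (events and non-events resampled separately,
#' so every resample retains both classes) with a percentile 95% interval.
#' Deterministic given `seed`.
#'
#' @inheritParams roc_auc
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A `roc_result`: `auc`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000, seed = 1L,
                             higher_predicts_event = TRUE, conf = 0.95) {
  auc <- roc_auc(scores, labels, higher_predicts_event)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- stratified_resample(labels)
      roc_auc(scores[idx], labels[idx], higher_predicts_event)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 6))
  structure(list(auc = auc, ci_low = min(ci[1], auc),
                 ci_high = max(ci[2], auc), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; %d bootstrap resamples)\n",
              x$auc, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Paired bootstrap test for an AUC difference
#'
#' Resamples patients (stratified by outcome), recomputes both AUCs on each
#' resample, and returns a two-sided p-value for the difference against
#' zero from the bootstrap distribution of `AUC(a) - AUC(b)`, with the
#' (k+1)/(B+1) small-sample correction. Symmetric in `scores_a`/`scores_b`.
#'
#' @param scores_a,scores_b Two score vectors aligned to the same patients.
#' @param labels 0/1 event labels.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @param higher_predicts_event Orientation, applied to both score vectors.
#' @return List with `auc_a`, `auc_b`, `delta`, `p_value`, `n_boot`, `seed`.
#' @export
compare_auc_bootstrap <- function(scores_a, scores_b, labels, n_boot = 2000,
                                  seed = 1L, higher_predicts_event = TRUE) {
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    stop("score vectors must align with labels", call. = FALSE)
  }
  auc_a <- roc_auc(scores_a, labels, higher_predicts_event)
  auc_b <- roc_auc(scores_b, labels, higher_predicts_event)
  deltas <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- stratified_resample(labels)
      roc_auc(scores_a[idx], labels[idx], higher_predicts_event) -
        roc_auc(scores_b[idx], labels[idx], higher_predicts_event)
    }, numeric(1))
  })
  p_low <- (sum(deltas <= 0) + 1) / (n_boot + 1)
  p_high <- (sum(deltas >= 0) + 1) / (n_boot + 1)
  list(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b,
       p_value = min(1, 2 * min(p_low, p_high)),
       n_boot = as.integer(n_boot), seed = as.integer(seed))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of survival over follow-up months; patients alive
#' at 36 months are right-censored there.
#'
#' @param times Positive follow-up times in months.
#' @param events 0/1 death indicators.
#' @return A `km_curve`: `time` grid (starting at 0), `surv` estimates,
#'   `n_risk` and `n_event` at each time.
#' @export
km_estimate <- function(times, events) {
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(events %in% c(0, 1))) {
    stop("events must be coded {0, 1}", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = c(0, fit$time), surv = c(1, fit$surv),
                 n_risk = c(length(times), fit$n.risk),
                 n_event = c(0, fit$n.event)),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' Standard (rho = 0) log-rank comparison of two survival experiences.
#' Invariant to swapping the groups. When neither group has any event the
#' statistic is 0 and the result is flagged.
#'
#' @param times_1,events_1 Follow-up and death indicators, group 1.
#' @param times_2,events_2 Follow-up and death indicators, group 2.
#' @return List with `chisq`, `df`, `p_value` and `no_events` flag.
#' @export
logrank_test <- function(times_1, events_1, times_2, events_2) {
  if (length(times_1) == 0 || length(times_2) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (sum(events_1) + sum(events_2) == 0) {
    return(list(chisq = 0, df = 1L, p_value = 1, no_events = TRUE))
  }
  times <- c(times_1, times_2)
  events <- c(events_1, events_2)
  group <- rep(1:2, c(length(times_1), length(times_2)))
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(chisq = unname(sd$chisq), df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       no_events = FALSE)
}

#' Mortality rate per 100 patient-years
#'
#' `100 * deaths / (total follow-up in years)`, with follow-up capped at 36
#' months per patient.
#'
#' @param times Positive follow-up times in months.
#' @param events 0/1 death indicators.
#' @return Deaths per 100 patient-years.
#' @export
mortality_rate_per100py <- function(times, events) {
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  py <- sum(pmin(times, 36)) / 12
  if (py <= 0) stop("zero total follow-up", call. = FALSE)
  100 * sum(events) / py
}

# Hosmer-Lemeshow goodness-of-fit over g risk groups.
hosmer_lemeshow <- function(y, p, g = 10) {
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1)))
  if (length(breaks) < 3) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                n_groups = length(breaks) - 1L))
  }
  grp <- cut(p, breaks = breaks, include.lowest = TRUE)
  obs <- tapply(y, grp, sum)
  expd <- tapply(p, grp, sum)
  n_g <- tapply(y, grp, length)
  keep <- !is.na(obs)
  obs <- obs[keep]; expd <- expd[keep]; n_g <- n_g[keep]
  stat <- sum((obs - expd)^2 / (expd * (1 - expd / n_g)))
  df <- length(obs) - 2L
  list(statistic = unname(stat), df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       n_groups = length(obs))
}

#' Nine-variable logistic comparator
#'
#' Maximum-likelihood logistic regression of poor 36-month survival on the
#' nine DIFE covariates, reported as odds ratios with Wald 95% confidence
#' intervals plus a Hosmer-Lemeshow calibration statistic over 10 risk
#' deciles. Covariates without variation are dropped and flagged;
#' quasi-separation (any |coefficient| > 15 or non-convergence) is flagged
#' rather than silently reported.
#'
#' @param cohort A `dife_cohort`.
#' @param variables Cohort columns to regress on (default: the nine DIFE
#'   covariates).
#' @return A `logistic_comparator`: the fitted `model`, a coefficient table
#'   (`estimate`, `odds_ratio`, CI bounds, `p_value`), the `calibration`
#'   list (statistic, df, p), `dropped` covariates and a `separation` flag.
#'   `predict()` returns per-patient predicted poor-survival probabilities
#'   (usable directly as a risk score).
#' @export
fit_logistic_comparator <- function(cohort,
                                    variables = c("scr_mgdl", "age",
                                                  "alb_gdl", "hb_gdl",
                                                  "bun_mgdl",
                                                  "phosphate_mmoll",
                                                  "heart_failure",
                                                  "diabetes", "female")) {
  y <- outcome_poor(cohort)
  if (length(unique(y)) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  dat <- as.data.frame(cohort)[, variables, drop = FALSE]
  constant <- vapply(dat, function(x) stats::var(x) == 0, logical(1))
  dropped <- names(dat)[constant]
  dat <- dat[, !constant, drop = FALSE]
  dat$.y <- y
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  table <- data.frame(
    term = rownames(cf),
    estimate = est,
    odds_ratio = exp(est),
    or_low = exp(est - stats::qnorm(0.975) * se),
    or_high = exp(est + stats::qnorm(0.975) * se),
    p_value = cf[, "Pr(>|z|)"],
    row.names = NULL
  )
  p_hat <- stats::fitted(fit)
  structure(list(
    model = fit,
    coefficients = table,
    calibration = hosmer_lemeshow(y, p_hat, g = 10),
    dropped = dropped,
    separation = !fit$converged || any(abs(est[-1]) > 15)
  ), class = "logistic_comparator")
}

#' @param object A `logistic_comparator`.
#' @param cohort Cohort to score (default: refit data if omitted).
#' @param ... Unused.
#' @rdname fit_logistic_comparator
#' @export
predict.logistic_comparator <- function(object, cohort = NULL, ...) {
  if (is.null(cohort)) return(stats::fitted(object$model))
  stats::predict(object$model, newdata = as.data.frame(cohort),
                 type = "response")
}

#' @export
print.logistic_comparator <- function(x, ...) {
  cat("<logistic_comparator>\n")
  print(x$coefficients, digits = 3, row.names = FALSE)
  cal <- x$calibration
  cat(sprintf("Hosmer-Lemeshow: %.2f on %d df (p = %.3f)\n",
              cal$statistic, cal$df, cal$p_value))
  if (length(x$dropped) > 0) {
    cat("dropped constant covariates:", paste(x$dropped, collapse = ", "),
        "\n")
  }
  if (x$separation) cat("warning: possible separation\n")
  invisible(x)
}
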