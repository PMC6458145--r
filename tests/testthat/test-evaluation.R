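test_that("confusion metrics match hand-computed 2x2 values", {
  perfect <- confusion_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  flipped <- confusion_metrics(c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(flipped$sensitivity, 0)
  expect_equal(flipped$specificity, 0)
  expect_equal(flipped$accuracy, 0)
  # TP 26, FN 31, TN 339, FP 108
  truth <- rep(c(1, 1, 0, 0), c(26, 31, 339, 108))
  pred <- rep(c(1, 0, 0, 1), c(26, 31, 339, 108))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$sensitivity, 26 / 57)
  expect_equal(cm$specificity, 339 / 447)
  expect_equal(cm$accuracy, 365 / 504)
  # single-class truth is flagged, not silently numeric
  deg <- confusion_metrics(c(1, 0), c(0, 0))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$sensitivity))
})

test_that("rank AUC equals the exhaustive pairwise oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    labels <- c(rep(1, 3), rbinom(n - 6, 1, 0.4), rep(0, 3))
    scores <- round(rnorm(n), 1)   # rounding forces ties
    expect_identical(roc_auc(scores, labels), oracle_auc(scores, labels))
    # reversing the scores gives the complement
    expect_equal(roc_auc(-scores, labels), 1 - roc_auc(scores, labels))
    # the declared orientation is honoured, never auto-flipped
    expect_equal(roc_auc(scores, labels, higher_predicts_event = FALSE),
                 roc_auc(-scores, labels))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(120)
  labels <- rbinom(120, 1, plogis(scores))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("bootstrap AUC CI is seeded, ordered and degenerate when separable", {
  set.seed(2)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, plogis(2 * scores))
  r1 <- bootstrap_auc_ci(scores, labels, n_boot = 200, seed = 99)
  r2 <- bootstrap_auc_ci(scores, labels, n_boot = 200, seed = 99)
  expect_identical(r1, r2)
  expect_true(r1$ci_low <= r1$auc && r1$auc <= r1$ci_high)
  sep <- bootstrap_auc_ci(c(1, 2, 3, 8, 9, 10), c(0, 0, 0, 1, 1, 1),
                          n_boot = 100, seed = 1)
  expect_equal(sep$ci_low, 1)
  expect_equal(sep$ci_high, 1)
})

test_that("paired bootstrap AUC comparison behaves at the null and under separation", {
  set.seed(3)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, plogis(scores))
  same <- compare_auc_bootstrap(scores, scores, labels, n_boot = 300,
                                seed = 4)
  expect_gte(same$p_value, 0.9)
  # strong vs useless scores on n = 400
  set.seed(8)
  labels2 <- rbinom(400, 1, 0.3)
  strong <- labels2 * 2 + rnorm(400, sd = 0.7)   # AUC ~ 0.9
  weak <- rnorm(400)                             # AUC ~ 0.5
  cmp <- compare_auc_bootstrap(strong, weak, labels2, n_boot = 500,
                               seed = 10)
  expect_lt(cmp$p_value, 0.01)
  # symmetric in the two score vectors
  swapped <- compare_auc_bootstrap(weak, strong, labels2, n_boot = 500,
                                   seed = 10)
  expect_equal(cmp$p_value, swapped$p_value)
  expect_equal(cmp$delta, -swapped$delta)
})

test_that("Kaplan-Meier estimate equals the survival oracle", {
  # no censoring: the curve is 1 - ECDF of the death times
  times <- c(2, 5, 5, 9, 14)
  km <- km_estimate(times, rep(1, 5))
  ecdf_surv <- 1 - ecdf(times)(km$time)
  expect_equal(km$surv, ecdf_surv)
  # all censored: survival stays at 1
  km_c <- km_estimate(c(10, 20, 36), c(0, 0, 0))
  expect_true(all(km_c$surv == 1))
  # worked 6-patient set: deaths at 3 and 10, censoring at 12, 36, 36, 36
  km6 <- km_estimate(c(3, 10, 12, 36, 36, 36), c(1, 1, 0, 0, 0, 0))
  expect_equal(km6$surv[km6$time == 3], 5 / 6)
  expect_equal(km6$surv[km6$time == 10], 5 / 6 * 4 / 5)
  # independent product-limit loop agrees at every death time
  set.seed(12)
  t_r <- round(runif(40, 1, 36))
  e_r <- rbinom(40, 1, 0.6)
  ora <- oracle_km(t_r, e_r)
  km_r <- km_estimate(t_r, e_r)
  expect_equal(km_r$surv[match(ora$time, km_r$time)], ora$surv)
  expect_true(all(diff(km_r$surv) <= 0))
  expect_equal(km_r$surv[1], 1)
  expect_error(km_estimate(c(-1, 3), c(1, 1)), "positive")
})

test_that("log-rank test matches the observed-minus-expected oracle", {
  t1 <- c(3, 6, 9, 12, 36); e1 <- c(1, 1, 1, 0, 0)
  t2 <- c(10, 20, 30, 36, 36); e2 <- c(1, 0, 1, 0, 0)
  got <- logrank_test(t1, e1, t2, e2)
  expect_equal(got$chisq, oracle_logrank(t1, e1, t2, e2), tolerance = 1e-10)
  # identical groups: statistic 0
  same <- logrank_test(t1, e1, t1, e1)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  # relabeling the groups changes nothing
  swapped <- logrank_test(t2, e2, t1, e1)
  expect_equal(got$chisq, swapped$chisq)
  # no events anywhere: flagged zero
  none <- logrank_test(c(5, 10), c(0, 0), c(7, 12), c(0, 0))
  expect_equal(none$chisq, 0)
  expect_true(none$no_events)
})

test_that("mortality rate per 100 patient-years follows the definition", {
  expect_equal(mortality_rate_per100py(c(36, 36, 36), c(0, 0, 0)), 0)
  # 2 deaths at 18 months among 10 patients, 8 survivors at 36 months:
  # 100 * 2 / (2*1.5 + 8*3) = 7.407...
  times <- c(18, 18, rep(36, 8))
  events <- c(1, 1, rep(0, 8))
  expect_equal(mortality_rate_per100py(times, events), 200 / 27)
  # doubling every follow-up halves the rate (below the 36-month cap)
  expect_equal(mortality_rate_per100py(c(6, 12), c(1, 0)) / 2,
               mortality_rate_per100py(c(12, 24), c(1, 0)))
  # follow-up beyond 36 months is capped
  expect_equal(mortality_rate_per100py(c(60, 36), c(0, 1)),
               mortality_rate_per100py(c(36, 36), c(0, 1)))
})

test_that("logistic comparator recovers simulated coefficients and calibrates", {
  set.seed(44)
  cfg <- synthetic_cohort_config(n = 4000, seed = 61)
  co <- generate_cohort(cfg)
  fit <- fit_logistic_comparator(co)
  expect_s3_class(fit$model, "glm")
  expect_false(fit$separation)
  # directions of the strong generator effects are recovered
  cf <- fit$coefficients
  get <- function(term) cf$estimate[cf$term == term]
  expect_gt(get("age"), 0)
  expect_lt(get("alb_gdl"), 0)
  expect_lt(get("hb_gdl"), 0)
  expect_gt(get("heart_failure"), 0)
  # odds ratios and CIs are consistent transforms of the estimates
  expect_equal(cf$odds_ratio, exp(cf$estimate))
  expect_true(all(cf$or_low < cf$odds_ratio & cf$odds_ratio < cf$or_high))
  # the truth is logistic in these covariates, so calibration should hold
  expect_gt(fit$calibration$p_value, 0.01)
  expect_equal(fit$calibration$df, 8)
})

test_that("constant covariates are dropped and flagged, not crashed on", {
  df <- tiny_cohort_df(n = 60, seed = 3)
  df$diabetes <- 0
  co <- as_cohort(df)
  fit <- fit_logistic_comparator(co)
  expect_true("diabetes" %in% fit$dropped)
  expect_false("diabetes" %in% fit$coefficients$term)
})

test_that("null-model calibration statistic has mean near its degrees of freedom", {
  # under a correctly specified model the Hosmer-Lemeshow statistic is
  # approximately chi-square(df = groups - 2)
  set.seed(77)
  stats <- replicate(60, {
    n <- 400
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.8 * x1 - 0.5 * x2))
    fit <- glm(y ~ x1 + x2, family = binomial())
    dife:::hosmer_lemeshow(y, fitted(fit), g = 10)$statistic
  })
  # mean within 4 MC standard errors of df = 8
  expect_lt(abs(mean(stats) - 8), 4 * sd(stats) / sqrt(length(stats)))
})
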