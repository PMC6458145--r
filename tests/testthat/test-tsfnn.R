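test_that("outlier removal flags exactly the extreme records", {
  co <- generate_cohort(synthetic_cohort_config(n = 300, seed = 14))
  clean <- remove_outliers(co, cutoff = 6)   # nothing is 6 SD out here
  expect_equal(nrow(clean), nrow(co))
  expect_equal(nrow(attr(clean, "removal_log")), 0)
  # inject a single 10-SD creatinine record (validated bounds are bypassed
  # deliberately: the filter must catch what validation would)
  df <- as.data.frame(co)
  df$scr_mgdl[5] <- mean(df$scr_mgdl) + 10 * sd(df$scr_mgdl)
  co2 <- structure(df, label = "x", class = c("dife_cohort", "data.frame"))
  clean2 <- remove_outliers(co2, cutoff = 6)
  expect_equal(nrow(clean2), nrow(co) - 1)
  log2 <- attr(clean2, "removal_log")
  expect_equal(log2$patient_id, df$patient_id[5])
  expect_equal(log2$variable, "scr_mgdl")
  # at the tighter default cutoff the injected record is still flagged on
  # creatinine, and the log always matches the number removed
  clean3 <- remove_outliers(co2, cutoff = 4)
  log3 <- attr(clean3, "removal_log")
  expect_true(any(log3$patient_id == df$patient_id[5] &
                    log3$variable == "scr_mgdl"))
  expect_gte(nrow(log3), nrow(co2) - nrow(clean3))
  expect_error(remove_outliers(co, cutoff = 0), "positive")
  # iqr rule runs and keeps the bulk of a clean cohort
  expect_gte(nrow(remove_outliers(co, rule = "iqr", cutoff = 3)),
             0.95 * nrow(co))
})

test_that("threshold selection matches a brute-force confusion computation", {
  set.seed(20)
  n <- 200
  scores <- runif(n, 25, 37)
  outcomes <- rbinom(n, 1, plogis(30 - scores))
  cands <- c(29, 30, 31, 32, 33)
  rep <- select_threshold(scores, outcomes, candidates = cands)
  expect_equal(rep$table$threshold, cands)
  for (i in seq_along(cands)) {
    pred <- as.integer(scores < cands[i])
    tp <- sum(pred == 1 & outcomes == 1)
    fn <- sum(pred == 0 & outcomes == 1)
    tn <- sum(pred == 0 & outcomes == 0)
    fp <- sum(pred == 1 & outcomes == 0)
    expect_equal(rep$table$sensitivity[i], tp / (tp + fn))
    expect_equal(rep$table$specificity[i], tn / (tn + fp))
    expect_equal(rep$table$accuracy[i], (tp + tn) / n)
    expect_equal(rep$table$n_pred_poor[i] + rep$table$n_pred_good[i], n)
  }
  # the chosen threshold maximizes accuracy, smaller threshold on ties
  best <- max(rep$table$accuracy)
  expect_equal(rep$chosen_threshold,
               min(rep$table$threshold[rep$table$accuracy == best]))
})

test_that("threshold selection is shift-invariant and handles separation", {
  scores <- c(20, 22, 24, 40, 42, 44)
  outcomes <- c(1, 1, 1, 0, 0, 0)
  sep <- select_threshold(scores, outcomes, candidates = 30)
  expect_equal(sep$table$sensitivity, 1)
  expect_equal(sep$table$specificity, 1)
  expect_equal(sep$table$accuracy, 1)
  set.seed(3)
  s <- runif(100, 25, 35)
  o <- rbinom(100, 1, 0.3)
  a <- select_threshold(s, o, candidates = 29:33)
  b <- select_threshold(s + 7.5, o, candidates = 29:33 + 7.5)
  expect_equal(a$table$accuracy, b$table$accuracy)
  expect_equal(a$chosen_threshold + 7.5, b$chosen_threshold)
  # mortality columns appear when follow-up is supplied
  times <- ifelse(o == 1, 12, 36)
  with_fu <- select_threshold(s, o, candidates = 30, times = times,
                              events = o)
  expect_false(is.na(with_fu$table$mortality_pred_poor))
  expect_error(select_threshold(s[1:5], o), "aligned")
})

test_that("PSO reduces a simple quadratic and its trace is monotone", {
  cfg <- pso_config(swarm_size = 15, max_iterations = 50, seed = 3,
                    bounds = cbind(lower = rep(-10, 4),
                                   upper = rep(10, 4)))
  target <- c(1, -2, 3, 0.5)
  res <- dife:::pso_minimize(function(x) sum((x - target)^2), cfg)
  expect_lt(res$value, 1e-2)
  expect_true(all(diff(res$trace) <= 0))
  res2 <- dife:::pso_minimize(function(x) sum((x - target)^2), cfg)
  expect_identical(res$par, res2$par)
})

test_that("fit_dife is seeded, beats the constant baseline, and traces monotonically", {
  co <- generate_cohort_from_params(synthetic_cohort_config(n = 400,
                                                            seed = 31))
  cfg <- fast_pso_config()
  fit <- fit_dife(co, pso = cfg)
  expect_s3_class(fit$params, "dife_parameters")
  expect_true(all(diff(fit$diagnostics$trace) <= 1e-12))
  expect_lt(fit$diagnostics$loss, fit$diagnostics$baseline_loss)
  expect_gt(fit$link[["s"]], 0)
  fit2 <- fit_dife(co, pso = cfg)
  expect_identical(unclass(fit$params), unclass(fit2$params))
  # single-outcome cohorts are rejected
  df <- as.data.frame(co)
  df$died_within_36m <- 0
  df$survival_months <- 36
  expect_error(fit_dife(as_cohort(df), pso = cfg), "both outcome groups")
})

test_that("fitted scores discriminate in the direction of the truth", {
  dev <- generate_cohort_from_params(synthetic_cohort_config(n = 700,
                                                             seed = 41))
  fit <- fit_dife(dev, pso = pso_config(swarm_size = 40,
                                        max_iterations = 150, seed = 41))
  sc <- predict(fit, dev)
  # lower fitted score must mean higher mortality (AUC of -score vs death)
  expect_gt(roc_auc(-sc, dev$died_within_36m), 0.6)
})

test_that("training loss never exceeds the constant-score baseline across replicates", {
  cfg <- fast_pso_config()
  for (r in 1:5) {
    co <- generate_cohort_from_params(
      synthetic_cohort_config(n = 250, seed = 500 + r))
    fit <- fit_dife(co, pso = cfg, early_stop = FALSE)
    expect_lte(fit$diagnostics$loss, fit$diagnostics$baseline_loss + 1e-9)
  }
})
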