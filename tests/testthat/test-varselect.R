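make_blobs <- function(n_per = 100, sep = 4, seed = 13) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(k) {
    cbind(rnorm(n_per, centers[k, 1]), rnorm(n_per, centers[k, 2]))
  }))
  y <- factor(rep(survival_class_levels <- c("lt12", "m12to36", "gt36"),
                  each = n_per),
              levels = c("lt12", "m12to36", "gt36"))
  list(X = X, y = y)
}

test_that("survival class boundaries follow the study convention", {
  months <- c(5, 11.9, 12, 24, 35.9, 36, 36)
  died <-   c(1, 1,    1,  1,  1,    1,  0)
  cls <- survival_class(months, died)
  expect_equal(as.character(cls),
               c("lt12", "lt12", "m12to36", "m12to36", "m12to36",
                 "m12to36", "gt36"))
})

test_that("RBM pretraining has the right shapes, is seeded, and learns", {
  set.seed(99)
  n <- 150
  z1 <- rnorm(n)
  X <- scale(cbind(z1 + rnorm(n, sd = 0.3), z1 + rnorm(n, sd = 0.3),
                   rnorm(n)))
  cfg <- klnn_config(hidden_units = 6, rbm_iterations = 40, seed = 5)
  rbm <- pretrain_rbm(X, cfg)
  expect_equal(dim(rbm$weights), c(3, 6))
  expect_length(rbm$visible_bias, 3)
  expect_length(rbm$hidden_bias, 6)
  rbm2 <- pretrain_rbm(X, cfg)
  expect_identical(rbm$weights, rbm2$weights)
  # reconstruction improves over training on correlated data
  expect_lt(rbm$reconstruction_error[40], rbm$reconstruction_error[1])
  # non-standardized input warns; degenerate input errors
  expect_warning(pretrain_rbm(X * 3, cfg), "z-scored")
  expect_error(pretrain_rbm(X[, 1, drop = FALSE], cfg), "2 columns")
})

test_that("the kernel classifier separates well-separated blobs", {
  blobs <- make_blobs(n_per = 100, sep = 4)
  cfg <- klnn_config(hidden_units = 8, n_landmarks = 40,
                     rbm_iterations = 20, sgd_iterations = 80, seed = 2)
  fit <- train_klnn(blobs$X, blobs$y, config = cfg)
  expect_gte(fit$training_accuracy, 0.95)
  # prediction returns the full class factor and a valid probability matrix
  pr <- predict(fit, blobs$X, type = "prob")
  expect_equal(dim(pr), c(300, 3))
  expect_equal(rowSums(pr), rep(1, 300), tolerance = 1e-9)
})

test_that("the classifier degrades to the majority rate without signal", {
  blobs <- make_blobs(n_per = 60, sep = 4)
  cfg <- fast_klnn_config()
  # constant features carry no information
  Xc <- matrix(1, nrow = 180, ncol = 3)
  fit <- train_klnn(Xc, blobs$y, config = cfg)
  maj <- max(table(blobs$y)) / length(blobs$y)
  expect_equal(fit$training_accuracy, maj, tolerance = 0.02)
  # permuted labels: CV accuracy near the majority proportion
  set.seed(6)
  y_perm <- sample(blobs$y)
  cv <- cv_accuracy(blobs$X, y_perm, cfg)
  expect_lt(abs(cv$mean_accuracy - maj), 0.12)
  expect_error(train_klnn(blobs$X, factor(rep("lt12", 180),
                                          levels = survival_class_levels())),
               "two classes")
})

test_that("cross-validation folds partition the records", {
  set.seed(4)
  for (n in c(23, 40)) {
    folds <- dife:::make_folds(n, 10)
    expect_length(folds, n)
    expect_setequal(unique(folds), 1:10)
    expect_lte(diff(range(table(folds))), 1)
  }
  expect_error(dife:::make_folds(5, 10), "fewer records")
})

test_that("cv accuracy is reproducible and close to a holdout estimate on separable data", {
  blobs <- make_blobs(n_per = 70, sep = 4, seed = 8)
  cfg <- klnn_config(hidden_units = 8, n_landmarks = 40,
                     rbm_iterations = 20, sgd_iterations = 80,
                     n_simulations = 2, n_folds = 5, seed = 7)
  cv1 <- cv_accuracy(blobs$X, blobs$y, cfg)
  cv2 <- cv_accuracy(blobs$X, blobs$y, cfg)
  expect_identical(cv1, cv2)
  expect_true(all(cv1$per_simulation >= 0 & cv1$per_simulation <= 1))
  expect_equal(cv1$mean_accuracy, mean(cv1$per_simulation))
  # 50/50 holdout estimate of the same classifier
  set.seed(9)
  idx <- sample(nrow(blobs$X), nrow(blobs$X) / 2)
  fit <- train_klnn(blobs$X[idx, ], blobs$y[idx], config = cfg)
  holdout <- mean(predict(fit, blobs$X[-idx, ]) == blobs$y[-idx])
  expect_lt(abs(cv1$mean_accuracy - holdout), 0.05)
})

test_that("subset search enumerates, ranks, and finds the signal variable", {
  df <- tiny_cohort_df(n = 120, seed = 15)
  # plant the class signal in haemoglobin only
  cls <- survival_class(df$survival_months, df$died_within_36m)
  df$hb_gdl <- 6 + 2 * as.integer(cls) + rnorm(nrow(df), sd = 0.2)
  co <- as_cohort(df)
  cands <- list(core = c("age", "female"),
                addons = c("hb_gdl", "potassium_mmoll"))
  cfg <- fast_klnn_config()
  res <- search_subsets(co, cands, strategy = "exhaustive_over_addons",
                        config = cfg)
  expect_equal(nrow(res), 4)   # 2^2 add-on combinations
  expect_true(all(diff(res$mean_accuracy) <= 0))
  expect_match(res$variables[1], "hb_gdl")
  # empty add-on set: single core subset
  res_core <- search_subsets(co, list(core = c("age", "female"),
                                      addons = character(0)),
                             config = cfg)
  expect_equal(nrow(res_core), 1)
  # full exhaustive over 3 candidates: subsets of size >= 2 of 3 variables
  res_full <- search_subsets(co, list(core = character(0),
                                      addons = c("age", "hb_gdl",
                                                 "potassium_mmoll")),
                             strategy = "full_exhaustive", config = cfg)
  expect_equal(nrow(res_full), 4)   # C(3,2) + C(3,3)
  expect_error(search_subsets(co, cands, strategy = "simulated_annealing"))
})
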