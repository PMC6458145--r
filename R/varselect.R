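#' @title Variable selection with an RBM-pretrained kernel classifier
#' @description Ranks candidate covariate subsets for the DIFE by the mean
#'   cross-validated accuracy of a three-class survival classifier: an RBF
#'   kernel feature map feeding a hidden layer whose weights are initialized
#'   by a Gaussian-Bernoulli restricted Boltzmann machine, topped by a
#'   softmax over the three survival classes (< 12 months, 12-36 months,
#'   > 36 months), trained by stochastic gradient descent on the multinomial
#'   log-likelihood.
#' @name varselect
NULL

survival_class_levels <- function() c("lt12", "m12to36", "gt36")

#' Three-level survival class from follow-up and event status
#'
#' `< 12` months maps to `lt12`; `[12, 36)` months to `m12to36`; 36 months
#' without a death event to `gt36`. A death at exactly 36 months counts as
#' `m12to36` (the death-month boundary belongs to the closed interval).
#'
#' @param survival_months Follow-up in months, capped at 36.
#' @param died_within_36m 0/1 death indicator.
#' @return Factor with levels `lt12`, `m12to36`, `gt36`.
#' @export
survival_class <- function(survival_months, died_within_36m) {
  stopifnot(length(survival_months) == length(died_within_36m))
  cls <- ifelse(survival_months < 12, "lt12",
         ifelse(survival_months < 36, "m12to36",
         ifelse(died_within_36m == 1, "m12to36", "gt36")))
  factor(cls, levels = survival_class_levels())
}

#' Configuration for the kernel classifier and its CV harness
#'
#' @param hidden_units Hidden-layer width (default 10).
#' @param kernel `"rbf"` or `"linear"` feature map.
#' @param bandwidth RBF bandwidth; `NULL` uses the median heuristic
#'   (median pairwise Euclidean distance on the training rows).
#' @param n_landmarks Number of landmark rows for the kernel feature map
#'   (default 50; capped at the training-set size).
#' @param rbm_iterations Contrastive-divergence epochs (default 100).
#' @param sgd_iterations SGD epochs for the classifier (default 100).
#' @param learning_rate Initial SGD/CD learning rate (default 0.05, with
#'   inverse-epoch decay; small enough to be stable on z-scored kernel
#'   features, large enough that the softmax layer separates cleanly
#'   separable classes within the default epoch budget).
#' @param batch_size Minibatch size (default 32).
#' @param n_simulations Independent CV repetitions (default 20); each
#'   repetition reshuffles the folds and redraws the initialization.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer master seed.
#' @return A `klnn_config` list.
#' @export
klnn_config <- function(hidden_units = 10, kernel = c("rbf", "linear"),
                        bandwidth = NULL, n_landmarks = 50,
                        rbm_iterations = 100, sgd_iterations = 100,
                        learning_rate = 0.05, batch_size = 32,
                        n_simulations = 20, n_folds = 10, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(hidden_units >= 1, rbm_iterations >= 1, sgd_iterations >= 1,
            n_simulations >= 1, n_folds >= 1, n_landmarks >= 1,
            learning_rate > 0, batch_size >= 1)
  structure(list(hidden_units = as.integer(hidden_units), kernel = kernel,
                 bandwidth = bandwidth, n_landmarks = as.integer(n_landmarks),
                 rbm_iterations = as.integer(rbm_iterations),
                 sgd_iterations = as.integer(sgd_iterations),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_simulations = as.integer(n_simulations),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "klnn_config")
}

median_heuristic_bandwidth <- function(X, max_rows = 200) {
  n <- nrow(X)
  idx <- if (n > max_rows) seq(1, n, length.out = max_rows) else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  bw <- stats::median(d[d > 0])
  if (!is.finite(bw) || bw <= 0) 1 else bw
}

# RBF (or linear) feature map against a fixed landmark matrix.
kernel_features <- function(X, landmarks, bandwidth, kernel = "rbf") {
  X <- as.matrix(X)
  if (kernel == "linear") return(X %*% t(landmarks))
  # squared distances via the expansion ||x||^2 + ||l||^2 - 2 x.l
  d2 <- outer(rowSums(X^2), rowSums(landmarks^2), "+") -
    2 * X %*% t(landmarks)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * bandwidth^2))
}

#' Pretrain a Gaussian-Bernoulli RBM
#'
#' Contrastive-divergence (CD-1) training of a restricted Boltzmann machine
#' with Gaussian (unit-variance) visible units and Bernoulli hidden units,
#' used to initialize the classifier's hidden layer. Inputs are expected
#' z-scored; a warning is raised when any column SD departs from 1 by more
#' than 0.1.
#'
#' @param X Numeric matrix (rows = cases, >= 2 columns), standardized.
#' @param config A [klnn_config()]; uses `hidden_units`, `rbm_iterations`,
#'   `learning_rate`, `batch_size` and `seed`.
#' @return List with `weights` (`ncol(X)` x `hidden_units`), `visible_bias`,
#'   `hidden_bias` and the per-epoch mean squared `reconstruction_error`.
#' @export
pretrain_rbm <- function(X, config = klnn_config()) {
  X <- as.matrix(X)
  if (nrow(X) == 0 || ncol(X) < 2) {
    stop("X must be non-empty with >= 2 columns", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(is.finite(sds) & abs(sds - 1) > 0.1)) {
    warning("input columns do not look z-scored (SD departs 1 by > 0.1)",
            call. = FALSE)
  }
  with_seed(config$seed, {
    n <- nrow(X); d <- ncol(X); m <- config$hidden_units
    W <- matrix(stats::rnorm(d * m, sd = 0.01), d, m)
    vb <- rep(0, d); hb <- rep(0, m)
    recon <- numeric(config$rbm_iterations)
    for (epoch in seq_len(config$rbm_iterations)) {
      lr <- config$learning_rate / (1 + (epoch - 1) / 20)
      ord <- sample.int(n)
      err <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        v0 <- X[idx, , drop = FALSE]
        ph0 <- sigmoid(sweep(v0 %*% W, 2, hb, "+"))
        h0 <- matrix(stats::rbinom(length(ph0), 1, ph0), nrow(ph0))
        # Gaussian visibles: reconstruction mean, unit variance
        v1 <- sweep(h0 %*% t(W), 1, 0, "+")
        v1 <- sweep(v1, 2, vb, "+")
        ph1 <- sigmoid(sweep(v1 %*% W, 2, hb, "+"))
        nb <- length(idx)
        W <- W + lr * (t(v0) %*% ph0 - t(v1) %*% ph1) / nb
        vb <- vb + lr * colMeans(v0 - v1)
        hb <- hb + lr * colMeans(ph0 - ph1)
        err <- err + sum((v0 - v1)^2)
      }
      recon[epoch] <- err / (n * d)
    }
    list(weights = W, visible_bias = vb, hidden_bias = hb,
         reconstruction_error = recon)
  })
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train the three-class kernel survival classifier
#'
#' Pipeline: z-score the covariates, map them through an RBF kernel feature
#' map against seeded landmark rows, pass the features through a sigmoid
#' hidden layer initialized from an RBM pretrained on those same features,
#' and read out class probabilities through a softmax layer. All layers are
#' then trained jointly by minibatch stochastic gradient descent on the
#' multinomial log-likelihood.
#'
#' @param X Numeric covariate matrix (raw scale; standardized internally).
#' @param y3 Factor of survival classes (levels [survival_class()]); at
#'   least two classes must be present.
#' @param init Optional RBM initialization from [pretrain_rbm()]; its weight
#'   matrix must match the kernel feature dimension (number of landmarks).
#'   `NULL` (default) pretrains one internally.
#' @param config A [klnn_config()].
#' @return A `klnn` classifier with `predict()` (class labels or
#'   probabilities) and a stored training accuracy.
#' @export
train_klnn <- function(X, y3, init = NULL, config = klnn_config()) {
  X <- as.matrix(X)
  y3 <- factor(y3, levels = survival_class_levels())
  if (anyNA(y3)) stop("labels outside the survival classes", call. = FALSE)
  if (nrow(X) != length(y3)) stop("dimension mismatch", call. = FALSE)
  if (length(unique(y3)) < 2) {
    stop("labels must cover at least two classes", call. = FALSE)
  }
  with_seed(config$seed, {
    n <- nrow(X)
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    Z <- sweep(sweep(X, 2, center), 2, scale, "/")
    L <- min(config$n_landmarks, n)
    land_idx <- sample.int(n, L)
    landmarks <- Z[land_idx, , drop = FALSE]
    bw <- config$bandwidth %||% median_heuristic_bandwidth(Z)
    Phi <- kernel_features(Z, landmarks, bw, config$kernel)
    # z-score the kernel features: the RBM assumes unit-variance Gaussian
    # visibles, and a centred hidden layer keeps gradients alive
    phi_center <- colMeans(Phi)
    phi_scale <- apply(Phi, 2, stats::sd)
    phi_scale[!is.finite(phi_scale) | phi_scale == 0] <- 1
    Phi <- sweep(sweep(Phi, 2, phi_center), 2, phi_scale, "/")
    if (is.null(init)) {
      rbm_cfg <- config
      rbm_cfg$seed <- sample.int(.Machine$integer.max - 1L, 1)
      init <- suppressWarnings(pretrain_rbm(Phi, rbm_cfg))
    }
    if (nrow(init$weights) != ncol(Phi) ||
        ncol(init$weights) != config$hidden_units) {
      stop("init dimensions do not match the kernel feature map",
           call. = FALSE)
    }
    W1 <- init$weights
    b1 <- init$hidden_bias
    K <- 3L
    W2 <- matrix(stats::rnorm(config$hidden_units * K, sd = 0.01),
                 config$hidden_units, K)
    b2 <- rep(0, K)
    Y <- diag(K)[as.integer(y3), , drop = FALSE]
    for (epoch in seq_len(config$sgd_iterations)) {
      lr <- config$learning_rate / (1 + (epoch - 1) / 20)
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        Phb <- Phi[idx, , drop = FALSE]
        H <- sigmoid(sweep(Phb %*% W1, 2, b1, "+"))
        P <- softmax_rows(sweep(H %*% W2, 2, b2, "+"))
        D2 <- (P - Y[idx, , drop = FALSE]) / length(idx)
        D1 <- (D2 %*% t(W2)) * H * (1 - H)
        W2 <- W2 - lr * t(H) %*% D2
        b2 <- b2 - lr * colSums(D2)
        W1 <- W1 - lr * t(Phb) %*% D1
        b1 <- b1 - lr * colSums(D1)
      }
    }
    model <- structure(list(center = center, scale = scale,
                            landmarks = landmarks, bandwidth = bw,
                            phi_center = phi_center, phi_scale = phi_scale,
                            kernel = config$kernel, W1 = W1, b1 = b1,
                            W2 = W2, b2 = b2,
                            levels = survival_class_levels()),
                       class = "klnn")
    model$training_accuracy <-
      mean(predict(model, X) == y3)
    model
  })
}

#' @param object A fitted `klnn` classifier.
#' @param newdata Covariate matrix on the raw scale.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @rdname train_klnn
#' @export
predict.klnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  Z <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale,
             "/")
  Phi <- kernel_features(Z, object$landmarks, object$bandwidth,
                         object$kernel)
  Phi <- sweep(sweep(Phi, 2, object$phi_center), 2, object$phi_scale, "/")
  H <- sigmoid(sweep(Phi %*% object$W1, 2, object$b1, "+"))
  P <- softmax_rows(sweep(H %*% object$W2, 2, object$b2, "+"))
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

# Shuffled fold assignment: a partition of 1..n into n_folds near-equal
# test folds.
make_folds <- function(n, n_folds) {
  if (n < n_folds) stop("fewer records than folds", call. = FALSE)
  sample(rep(seq_len(n_folds), length.out = n))
}

#' Repeated cross-validated accuracy of the kernel survival classifier
#'
#' Runs `n_simulations` independent repetitions; each repetition reshuffles
#' the fold assignment and redraws the initialization seed, trains on the
#' complement of each test fold, and pools the held-out predictions into a
#' simulation-level accuracy. The reported value is the mean of the
#' simulation-level accuracies.
#'
#' @inheritParams train_klnn
#' @return List with `mean_accuracy` and `per_simulation` accuracies.
#' @export
cv_accuracy <- function(X, y3, config = klnn_config()) {
  X <- as.matrix(X)
  y3 <- factor(y3, levels = survival_class_levels())
  n <- nrow(X)
  if (n < config$n_folds) stop("fewer records than folds", call. = FALSE)
  sim_seeds <- derive_seeds(config$seed, 2L * config$n_simulations)
  acc <- numeric(config$n_simulations)
  for (s in seq_len(config$n_simulations)) {
    folds <- with_seed(sim_seeds[2 * s - 1], make_folds(n, config$n_folds))
    pred <- factor(rep(NA_character_, n), levels = survival_class_levels())
    for (f in seq_len(config$n_folds)) {
      test <- folds == f
      cfg <- config
      cfg$seed <- (sim_seeds[2 * s] + f) %% (.Machine$integer.max - 1L)
      fit <- train_klnn(X[!test, , drop = FALSE], droplevels(y3[!test]),
                        init = NULL, config = cfg)
      pred[test] <- predict(fit, X[test, , drop = FALSE])
    }
    acc[s] <- mean(pred == y3)
  }
  list(mean_accuracy = mean(acc), per_simulation = acc)
}

#' Candidate variables for the DIFE
#'
#' The 13 candidates: the five MDRD-equation variables (age, sex,
#' creatinine, BUN, albumin) and eight further clinical factors
#' (haemoglobin, potassium, phosphate, heart failure, vomiting, oedema
#' grade 2+, uraemic encephalopathy, diabetes).
#'
#' @return Named list with components `core` (the five always-included
#'   MDRD variables) and `addons` (the eight optional factors), in
#'   canonical cohort column names.
#' @export
dife_candidates <- function() {
  list(core = c("age", "female", "scr_mgdl", "bun_mgdl", "alb_gdl"),
       addons = c("hb_gdl", "potassium_mmoll", "phosphate_mmoll",
                  "heart_failure", "vomiting", "oedema2plus",
                  "uraemic_encephalopathy", "diabetes"))
}

#' Rank candidate-variable subsets by cross-validated accuracy
#'
#' Evaluates [cv_accuracy()] for each subset under the chosen strategy and
#' returns the subsets sorted by mean accuracy (descending), ties broken by
#' smaller subset and then lexicographically.
#'
#' @param cohort A `dife_cohort`.
#' @param candidates Named list with `core` and `addons` character vectors
#'   of cohort column names (default [dife_candidates()]).
#' @param strategy `"exhaustive_over_addons"` (default: core always in, all
#'   2^8 add-on combinations), `"full_exhaustive"` (every subset of size
#'   >= 2 of all candidates), or `"greedy"` (forward selection from the
#'   core).
#' @param config A [klnn_config()].
#' @return Data frame with columns `variables` (comma-joined names),
#'   `n_variables`, `mean_accuracy` and a list column `accuracies` of
#'   per-simulation values.
#' @export
search_subsets <- function(cohort, candidates = dife_candidates(),
                           strategy = c("exhaustive_over_addons",
                                        "full_exhaustive", "greedy"),
                           config = klnn_config()) {
  strategy <- match.arg(strategy)
  all_vars <- c(candidates$core, candidates$addons)
  missing <- setdiff(all_vars, names(cohort))
  if (length(missing) > 0) {
    stop("candidate variables not in cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  y3 <- survival_class(cohort$survival_months, cohort$died_within_36m)
  eval_subset <- function(vars, seed_offset) {
    cfg <- config
    cfg$seed <- (config$seed + seed_offset) %% (.Machine$integer.max - 1L)
    cv <- cv_accuracy(as.matrix(cohort[, vars, drop = FALSE]), y3, cfg)
    data.frame(variables = paste(sort(vars), collapse = ","),
               n_variables = length(vars),
               mean_accuracy = cv$mean_accuracy,
               accuracies = I(list(cv$per_simulation)))
  }
  subsets <- switch(strategy,
    exhaustive_over_addons = {
      k <- length(candidates$addons)
      lapply(seq_len(2^k) - 1L, function(mask) {
        on <- candidates$addons[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
        c(candidates$core, on)
      })
    },
    full_exhaustive = {
      k <- length(all_vars)
      out <- lapply(seq_len(2^k) - 1L, function(mask) {
        all_vars[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
      })
      out[vapply(out, length, integer(1)) >= 2]
    },
    greedy = NULL
  )
  if (strategy == "greedy") {
    current <- candidates$core
    rows <- list(eval_subset(current, 0L))
    best <- rows[[1]]$mean_accuracy
    remaining <- candidates$addons
    offset <- 1L
    repeat {
      if (length(remaining) == 0) break
      trials <- lapply(remaining, function(v) {
        offset <<- offset + 1L
        eval_subset(c(current, v), offset)
      })
      accs <- vapply(trials, function(tr) tr$mean_accuracy, numeric(1))
      if (max(accs) <= best) break
      pick <- which.max(accs)
      current <- c(current, remaining[pick])
      remaining <- remaining[-pick]
      best <- max(accs)
      rows <- c(rows, trials[pick])
    }
    res <- do.call(rbind, rows)
  } else {
    res <- do.call(rbind, Map(eval_subset, subsets,
                              seq_along(subsets) - 1L))
  }
  ord <- order(-res$mean_accuracy, res$n_variables, res$variables)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
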