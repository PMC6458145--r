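# Independent oracles: deliberately plain, scalar-by-scalar arithmetic,
# sharing no code with the package implementations they check.

oracle_weighting_w <- function(row, params) {
  eta <- params[["t1"]] + params[["t2"]] * row$scr +
    params[["t3"]] * row$alb + params[["t4"]] * row$hb +
    params[["t5"]] * log(row$bun) + params[["t6"]] * row$phosphate
  1 / (1 + exp(eta))
}

oracle_dife_score <- function(row, params) {
  w <- oracle_weighting_w(row, params)
  prod_term <- params[["p2"]] *
    row$scr^params[["p3"]] *
    (log(row$age))^params[["p4"]] *
    row$alb^params[["p5"]] *
    row$hb^params[["p6"]] *
    (log(row$bun))^params[["p7"]] *
    row$phosphate^params[["p8"]]
  params[["p15"]] + params[["p1"]] * w *
    (prod_term + params[["p9"]] * exp(row$heart_failure) +
       params[["p10"]] * exp(row$diabetes) +
       params[["p11"]] * exp(row$female) + params[["p16"]])
}

# O(n^2) pairwise AUC: P(case score > control score) + 0.5 P(tie).
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (x in cases) {
    for (y in controls) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(cases) * length(controls))
}

# Product-limit estimator by explicit loop over distinct event times.
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# Two-group log-rank by explicit observed-minus-expected accumulation.
oracle_logrank <- function(times_1, events_1, times_2, events_2) {
  times <- c(times_1, times_2)
  events <- c(events_1, events_2)
  group <- rep(1:2, c(length(times_1), length(times_2)))
  ts <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  o_minus_e^2 / v
}

# Random-but-valid parameter sets and score inputs for oracle sweeps.
random_dife_parameters <- function() {
  vals <- c(stats::runif(13, -5, 5), stats::runif(6, -2, 2))
  dife_parameters(stats::setNames(
    as.list(vals), c(paste0("p", c(1:11, 15, 16)), paste0("t", 1:6))))
}

random_dife_input <- function(n = 1) {
  data.frame(
    scr = stats::runif(n, 2, 25),
    age = stats::runif(n, 18, 85),
    alb = stats::runif(n, 1.5, 5.5),
    hb = stats::runif(n, 4, 16),
    bun = stats::runif(n, 20, 200),
    phosphate = stats::runif(n, 0.5, 4),
    heart_failure = stats::rbinom(n, 1, 0.3),
    diabetes = stats::rbinom(n, 1, 0.25),
    female = stats::rbinom(n, 1, 0.4)
  )
}

# A small fully-specified cohort data frame for I/O and metric tests.
tiny_cohort_df <- function(n = 8, seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    died <- rbinom(n, 1, 0.4)
    data.frame(
      patient_id = sprintf("T%03d", seq_len(n)),
      female = rbinom(n, 1, 0.4),
      age = round(runif(n, 20, 80)),
      scr_mgdl = round(runif(n, 4, 15), 1),
      bun_mgdl = round(runif(n, 40, 120), 1),
      alb_gdl = round(runif(n, 2, 5), 1),
      hb_gdl = round(runif(n, 5, 12), 1),
      phosphate_mmoll = round(runif(n, 1, 3), 2),
      potassium_mmoll = round(runif(n, 3.5, 6), 2),
      heart_failure = rbinom(n, 1, 0.3),
      vomiting = rbinom(n, 1, 0.3),
      oedema2plus = rbinom(n, 1, 0.4),
      uraemic_encephalopathy = rep(0, n),
      diabetes = rbinom(n, 1, 0.25),
      survival_months = ifelse(died == 1, round(runif(n, 1, 35), 1), 36),
      died_within_36m = died
    )
  })
}

# Tiny configs so unit tests exercise full code paths quickly.
fast_klnn_config <- function(...) {
  klnn_config(hidden_units = 5, n_landmarks = 20, rbm_iterations = 10,
              sgd_iterations = 30, n_simulations = 2, n_folds = 3,
              seed = 7, ...)
}

fast_pso_config <- function(...) {
  pso_config(swarm_size = 20, max_iterations = 60, n_folds = 5,
             seed = 7, ...)
}
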