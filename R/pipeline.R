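#' @title Develop/validate pipeline orchestration
#' @description End-to-end runs: `run_develop` performs (optional) variable
#'   selection, outlier removal, PSO fitting, threshold selection and the
#'   logistic comparator fit on a development cohort; `run_validate` scores
#'   a validation cohort, computes confusion metrics, bootstrap ROC
#'   comparisons against the logistic and eGFR comparators, Kaplan-Meier
#'   curves per predicted group, and the eGFR threshold sweep. Every
#'   artifact embeds the seed and a hash of the configuration that produced
#'   it.
#' @name cli_pipeline
NULL

config_hash <- function(config) {
  # canonical JSON -> md5 (via the file-based hasher in base tools)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  drop_fn <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) return(lapply(x, drop_fn))
    x
  }
  jsonlite::write_json(drop_fn(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for artifacts (created if absent).
#' @param seed Master seed; all stage seeds derive from it.
#' @param dev_cohort,val_cohort A `dife_cohort`, a CSV path, or `NULL` to
#'   generate synthetic cohorts from `synthetic_config`.
#' @param synthetic_config A [synthetic_cohort_config()] used when a cohort
#'   is not supplied; the validation draw uses `val_n` patients and a
#'   derived seed.
#' @param val_n Validation-cohort size for synthetic generation
#'   (default 504).
#' @param pso A [pso_config()] (its seed is overridden by the derived
#'   stage seed).
#' @param run_varselect Run the (expensive) subset search (default
#'   `FALSE`; the fixed nine-variable DIFE is fitted either way).
#' @param klnn A [klnn_config()] for the subset search.
#' @param candidate_thresholds Candidate decision thresholds
#'   (default `29:33`).
#' @param egfr_thresholds eGFR cutoffs for the conventional-assessment
#'   sweep (default `5:9` mL/min/1.73 m^2).
#' @param n_boot Bootstrap resamples for ROC comparisons (default 2000).
#' @param outlier_cutoff Z-score cutoff for [remove_outliers()]
#'   (default 4).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("dife_run_"), seed = 1L,
                       dev_cohort = NULL, val_cohort = NULL,
                       synthetic_config = synthetic_cohort_config(),
                       val_n = 504L, pso = pso_config(),
                       run_varselect = FALSE, klnn = klnn_config(),
                       candidate_thresholds = 29:33,
                       egfr_thresholds = 5:9, n_boot = 2000,
                       outlier_cutoff = 4) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 dev_cohort = dev_cohort, val_cohort = val_cohort,
                 synthetic_config = synthetic_config,
                 val_n = as.integer(val_n), pso = pso,
                 run_varselect = run_varselect, klnn = klnn,
                 candidate_thresholds = candidate_thresholds,
                 egfr_thresholds = egfr_thresholds,
                 n_boot = as.integer(n_boot),
                 outlier_cutoff = outlier_cutoff),
            class = "run_config")
}

resolve_cohort <- function(spec, config, role) {
  if (inherits(spec, "dife_cohort")) return(spec)
  if (is.character(spec)) return(read_cohort(spec, label = role))
  seeds <- derive_seeds(config$seed, 2L)
  syn <- config$synthetic_config
  if (role == "development") {
    syn$seed <- seeds[1]
  } else {
    syn$n <- config$val_n
    syn$seed <- seeds[2]
  }
  generate_cohort(syn, label = paste0("synthetic-", role))
}

manifest_for <- function(config, stage, extra = list()) {
  c(list(stage = stage, seed = config$seed,
         config_hash = config_hash(config),
         package_version = as.character(utils::packageVersion("dife")),
         timestamp = format(Sys.time(), tz = "UTC")),
    extra)
}

#' Run the development stage
#'
#' Resolves the development cohort (given, read, or generated), optionally
#' ranks candidate-variable subsets, removes outliers, fits the DIFE by
#' PSO, selects the decision threshold, and fits the logistic comparator.
#' Writes `params.json`, `threshold_report.csv`, `logistic_comparator.csv`,
#' optionally `varselect_ranking.csv`, and `run_manifest_develop.json`
#' under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted objects and artifact paths.
#' @export
run_develop <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_seeds <- derive_seeds(config$seed, 4L)
  dev <- resolve_cohort(config$dev_cohort, config, "development")
  message(sprintf("[develop] cohort: %d patients, %d deaths",
                  nrow(dev), sum(dev$died_within_36m)))
  ranking <- NULL
  if (isTRUE(config$run_varselect)) {
    klnn <- config$klnn
    klnn$seed <- stage_seeds[1]
    ranking <- search_subsets(dev, config = klnn)
    utils::write.csv(ranking[, c("variables", "n_variables",
                                 "mean_accuracy")],
                     file.path(config$out_dir, "varselect_ranking.csv"),
                     row.names = FALSE)
  }
  cleaned <- remove_outliers(dev, rule = "zscore",
                             cutoff = config$outlier_cutoff)
  message(sprintf("[develop] outlier removal: %d -> %d records",
                  nrow(dev), nrow(cleaned)))
  pso <- config$pso
  pso$seed <- stage_seeds[2]
  fit <- fit_dife(cleaned, pso = pso)
  scores <- predict(fit, cleaned)
  report <- select_threshold(scores, outcome_poor(cleaned),
                             candidates = config$candidate_thresholds,
                             times = cleaned$survival_months,
                             events = cleaned$died_within_36m)
  comparator <- fit_logistic_comparator(cleaned)
  params_path <- file.path(config$out_dir, "params.json")
  write_dife_parameters(fit$params, params_path)
  jsonlite::write_json(
    list(c = unname(fit$link["c"]), s = unname(fit$link["s"]),
         chosen_threshold = report$chosen_threshold),
    file.path(config$out_dir, "link.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$table,
                   file.path(config$out_dir, "threshold_report.csv"),
                   row.names = FALSE)
  utils::write.csv(comparator$coefficients,
                   file.path(config$out_dir, "logistic_comparator.csv"),
                   row.names = FALSE)
  manifest <- manifest_for(config, "develop", list(
    n_development = nrow(dev), n_after_outliers = nrow(cleaned),
    n_removed = nrow(dev) - nrow(cleaned),
    chosen_threshold = report$chosen_threshold,
    pso_loss = fit$diagnostics$loss,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 "run_manifest_develop.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("[develop] threshold %s; loss %.4f; %.1fs",
                  report$chosen_threshold, fit$diagnostics$loss,
                  manifest$elapsed_s))
  invisible(list(cohort = dev, cleaned = cleaned, fit = fit,
                 threshold_report = report, comparator = comparator,
                 varselect = ranking, params_path = params_path,
                 out_dir = config$out_dir))
}

#' Run the validation stage
#'
#' Scores the validation cohort with fitted parameters (from
#' `develop$fit` or `params.json` in `config$out_dir`), applies the chosen
#' threshold, and computes: confusion metrics; AUCs with bootstrap CIs for
#' the DIFE, the logistic comparator and both (negated) eGFR comparators;
#' paired bootstrap AUC-difference p-values; Kaplan-Meier curves and the
#' log-rank test across predicted groups; group mortality rates; and the
#' eGFR threshold sweep (5-9 mL/min/1.73 m^2). Writes `metrics.json`,
#' `roc_comparison.csv`, `km_groups.csv` and
#' `run_manifest_validate.json`.
#'
#' @param config A [run_config()].
#' @param develop Result of [run_develop()] (optional; otherwise artifacts
#'   are reloaded from `config$out_dir`, and the logistic comparator is
#'   refit on the development cohort).
#' @return Invisibly, a list with the metrics and artifact paths.
#' @export
run_validate <- function(config, develop = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_seeds <- derive_seeds(config$seed + 1L, 4L)
  if (is.null(develop)) {
    params_path <- file.path(config$out_dir, "params.json")
    if (!file.exists(params_path)) {
      stop("params.json not found in out_dir; run run_develop() first",
           call. = FALSE)
    }
    params <- read_dife_parameters(params_path)
    link <- jsonlite::read_json(file.path(config$out_dir, "link.json"),
                                simplifyVector = TRUE)
    threshold <- link$chosen_threshold
    dev_cohort <- resolve_cohort(config$dev_cohort, config, "development")
    comparator <- fit_logistic_comparator(
      remove_outliers(dev_cohort, cutoff = config$outlier_cutoff))
  } else {
    params <- develop$fit$params
    threshold <- develop$threshold_report$chosen_threshold
    comparator <- develop$comparator
  }
  val <- resolve_cohort(config$val_cohort, config, "validation")
  message(sprintf("[validate] cohort: %d patients, %d deaths",
                  nrow(val), sum(val$died_within_36m)))
  truth_poor <- outcome_poor(val)
  scores <- dife_score(dife_input_from_cohort(val), params)
  pred_poor <- as.integer(scores < threshold)
  conf <- confusion_metrics(pred_poor, truth_poor)
  # comparator scores, all oriented so higher = higher predicted mortality
  risk_dife <- -scores
  risk_logistic <- as.numeric(predict(comparator, val))
  risk_cmdrd <- -egfr_cmdrd(val$scr_mgdl, val$age, val$bun_mgdl,
                            val$alb_gdl, val$female)
  risk_ckdepi <- -egfr_ckdepi(val$scr_mgdl, val$age, val$female)
  risks <- list(dife = risk_dife, logistic = risk_logistic,
                cmdrd = risk_cmdrd, ckdepi = risk_ckdepi)
  roc <- lapply(seq_along(risks), function(i) {
    bootstrap_auc_ci(risks[[i]], truth_poor, n_boot = config$n_boot,
                     seed = stage_seeds[1] + i)
  })
  names(roc) <- names(risks)
  comparisons <- lapply(2:4, function(i) {
    compare_auc_bootstrap(risk_dife, risks[[i]], truth_poor,
                          n_boot = config$n_boot,
                          seed = stage_seeds[2] + i)
  })
  names(comparisons) <- paste0("dife_vs_", names(risks)[2:4])
  grp_poor <- pred_poor == 1
  km_poor <- if (any(grp_poor)) {
    km_estimate(val$survival_months[grp_poor],
                val$died_within_36m[grp_poor])
  } else NULL
  km_good <- if (any(!grp_poor)) {
    km_estimate(val$survival_months[!grp_poor],
                val$died_within_36m[!grp_poor])
  } else NULL
  lr <- if (any(grp_poor) && any(!grp_poor)) {
    logrank_test(val$survival_months[grp_poor],
                 val$died_within_36m[grp_poor],
                 val$survival_months[!grp_poor],
                 val$died_within_36m[!grp_poor])
  } else {
    list(chisq = NA_real_, df = 1L, p_value = NA_real_, no_events = NA)
  }
  egfr_sweep <- do.call(rbind, lapply(config$egfr_thresholds, function(th) {
    late <- as.integer(-risk_cmdrd < th)  # eGFR below cutoff = late start
    cm <- confusion_metrics(late, truth_poor)
    data.frame(egfr_threshold = th, n_late = sum(late),
               n_early = sum(late == 0), sensitivity = cm$sensitivity,
               specificity = cm$specificity, accuracy = cm$accuracy)
  }))
  metrics <- list(
    seed = config$seed, config_hash = config_hash(config),
    threshold = threshold, n_validation = nrow(val),
    n_pred_poor = sum(pred_poor), n_pred_good = sum(pred_poor == 0),
    sensitivity = conf$sensitivity, specificity = conf$specificity,
    accuracy = conf$accuracy,
    mortality_per100py_pred_poor = if (any(grp_poor)) {
      mortality_rate_per100py(val$survival_months[grp_poor],
                              val$died_within_36m[grp_poor])
    } else NA,
    mortality_per100py_pred_good = if (any(!grp_poor)) {
      mortality_rate_per100py(val$survival_months[!grp_poor],
                              val$died_within_36m[!grp_poor])
    } else NA,
    auc = lapply(roc, function(r) {
      list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high)
    }),
    auc_comparisons = lapply(comparisons, function(cp) {
      list(delta = cp$delta, p_value = cp$p_value)
    }),
    logrank = list(chisq = lr$chisq, p_value = lr$p_value),
    egfr_sweep = egfr_sweep
  )
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  roc_tab <- data.frame(
    model = names(roc),
    auc = vapply(roc, function(r) r$auc, numeric(1)),
    ci_low = vapply(roc, function(r) r$ci_low, numeric(1)),
    ci_high = vapply(roc, function(r) r$ci_high, numeric(1)),
    p_vs_dife = c(NA, vapply(comparisons, function(cp) cp$p_value,
                             numeric(1)))
  )
  utils::write.csv(roc_tab, file.path(config$out_dir, "roc_comparison.csv"),
                   row.names = FALSE)
  km_tab <- rbind(
    if (!is.null(km_poor)) {
      data.frame(group = "pred_poor", time = km_poor$time,
                 surv = km_poor$surv, n_risk = km_poor$n_risk)
    },
    if (!is.null(km_good)) {
      data.frame(group = "pred_good", time = km_good$time,
                 surv = km_good$surv, n_risk = km_good$n_risk)
    }
  )
  utils::write.csv(km_tab, file.path(config$out_dir, "km_groups.csv"),
                   row.names = FALSE)
  manifest <- manifest_for(config, "validate", list(
    n_validation = nrow(val),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 "run_manifest_validate.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf(
    "[validate] acc %.3f sens %.3f spec %.3f; AUC dife %.3f; %.1fs",
    conf$accuracy, conf$sensitivity, conf$specificity, roc$dife$auc,
    manifest$elapsed_s))
  invisible(list(metrics = metrics, roc = roc, comparisons = comparisons,
                 km = list(pred_poor = km_poor, pred_good = km_good),
                 logrank = lr, egfr_sweep = egfr_sweep, scores = scores,
                 out_dir = config$out_dir))
}
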