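#' @title The DIFE score
#' @description Evaluation of the dialysis-initiation fuzzy-equation score
#'   `Y` and its sigmoid weighting multiplier `W`, classification at a score
#'   threshold, and JSON parameter-file I/O.
#'
#'   The score over nine covariates (Scr and BUN in mg/dL, Alb and Hb in
#'   g/dL, phosphate P in mmol/L, age in years, and 0/1 heart failure HF,
#'   diabetes DM and female indicators) is
#'
#'   \deqn{Y = P_{15} + P_1 W (P_2\,Scr^{P_3} (\ln age)^{P_4} Alb^{P_5}
#'     Hb^{P_6} (\ln BUN)^{P_7} P^{P_8} + P_9 e^{HF} + P_{10} e^{DM} +
#'     P_{11} e^{female} + P_{16})}
#'
#'   with weighting multiplier
#'
#'   \deqn{W = (1 + \exp(T_1 + T_2\,Scr + T_3\,Alb + T_4\,Hb +
#'     T_5 \ln BUN + T_6 P))^{-1}.}
#' @name dife
NULL

dife_param_names <- function() {
  c(paste0("p", c(1:11, 15, 16)), paste0("t", 1:6))
}

dife_input_names <- function() {
  c("scr", "age", "alb", "hb", "bun", "phosphate",
    "heart_failure", "diabetes", "female")
}

#' Construct a DIFE parameter set
#'
#' The 13 consequent parameters `p1`...`p11`, `p15`, `p16` and the 6 gate
#' parameters `t1`...`t6` of the score. All must be finite.
#'
#' @param ... Named numeric scalars covering exactly the 19 parameter names,
#'   or a single named list/vector of them.
#' @return A `dife_parameters` object (named numeric vector).
#' @export
dife_parameters <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) &&
      (is.list(args[[1]]) || length(args[[1]]) > 1)) {
    args <- as.list(args[[1]])
  }
  wanted <- dife_param_names()
  missing <- setdiff(wanted, names(args))
  extra <- setdiff(names(args), wanted)
  if (length(missing) > 0) {
    stop("parameter error: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra) > 0) {
    stop("parameter error: unknown ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  x <- vapply(args[wanted], as.numeric, numeric(1))
  if (any(!is.finite(x))) {
    stop("parameter error: all parameters must be finite", call. = FALSE)
  }
  structure(x, class = "dife_parameters")
}

#' @export
print.dife_parameters <- function(x, ...) {
  cat("<dife_parameters>\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Read DIFE parameters from a JSON file
#'
#' The file must contain exactly the keys `p1`...`p11`, `p15`, `p16`,
#' `t1`...`t6`; loading fails loudly on missing or extra keys.
#'
#' @param path Path to the JSON parameter file.
#' @return A `dife_parameters` object.
#' @export
read_dife_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dife_parameters(raw)
}

#' Write DIFE parameters to a JSON file
#'
#' @param params A `dife_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dife_parameters <- function(params, path) {
  stopifnot(inherits(params, "dife_parameters"))
  jsonlite::write_json(as.list(unclass(params)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

check_dife_input <- function(input) {
  input <- as.data.frame(input)
  missing <- setdiff(dife_input_names(), names(input))
  if (length(missing) > 0) {
    stop("missing input field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (v in c("scr", "alb", "hb", "phosphate")) {
    if (any(!is.finite(input[[v]])) || any(input[[v]] <= 0)) {
      stop_domain(v, " must be strictly positive and finite")
    }
  }
  if (any(!is.finite(input$age)) || any(input$age <= 1)) {
    stop_domain("age must exceed 1 year (ln(age) > 0)")
  }
  if (any(!is.finite(input$bun)) || any(input$bun <= 1)) {
    stop_domain("bun must exceed 1 mg/dL (ln(BUN) > 0)")
  }
  for (v in c("heart_failure", "diabetes", "female")) {
    if (!all(input[[v]] %in% c(0, 1))) {
      stop_domain(v, " must be coded {0, 1}")
    }
  }
  input
}

#' Map a cohort table to DIFE score inputs
#'
#' Selects and renames the nine score covariates from the canonical cohort
#' columns (units: Scr/BUN mg/dL, Alb/Hb g/dL, phosphate mmol/L).
#'
#' @param cohort A `dife_cohort` or data frame in the canonical schema.
#' @return Data frame with columns [dife_input_names()].
#' @export
dife_input_from_cohort <- function(cohort) {
  data.frame(scr = cohort$scr_mgdl, age = cohort$age, alb = cohort$alb_gdl,
             hb = cohort$hb_gdl, bun = cohort$bun_mgdl,
             phosphate = cohort$phosphate_mmoll,
             heart_failure = cohort$heart_failure,
             diabetes = cohort$diabetes, female = cohort$female)
}

#' The sigmoid weighting multiplier W
#'
#' `W = 1 / (1 + exp(t1 + t2 Scr + t3 Alb + t4 Hb + t5 ln(BUN) + t6 P))`,
#' computed with an overflow-safe sigmoid so extreme gate parameters
#' saturate to 0 or 1 without numerical overflow. Strictly inside (0, 1)
#' for finite arguments.
#'
#' @param input Data frame (or single-row list) with the
#'   [dife_input_names()] fields; vectorized over rows.
#' @param params A `dife_parameters` object.
#' @return Numeric vector of multipliers in (0, 1).
#' @export
weighting_w <- function(input, params) {
  stopifnot(inherits(params, "dife_parameters"))
  input <- check_dife_input(input)
  eta <- params[["t1"]] + params[["t2"]] * input$scr +
    params[["t3"]] * input$alb + params[["t4"]] * input$hb +
    params[["t5"]] * log(input$bun) + params[["t6"]] * input$phosphate
  if (any(!is.finite(eta))) {
    stop_domain("non-finite linear predictor in weighting multiplier")
  }
  sigmoid(-eta)
}

#' Evaluate the DIFE score Y
#'
#' Lower scores indicate worse predicted 3-year survival and hence more
#' urgent haemodialysis initiation. Natural logarithms throughout.
#'
#' @inheritParams weighting_w
#' @return Numeric vector of scores.
#' @examples
#' params <- dife_parameters(stats::setNames(
#'   rep(1, 19), c(paste0("p", c(1:11, 15, 16)), paste0("t", 1:6))))
#' dife_score(data.frame(scr = 6.6, age = 65, alb = 3, hb = 8, bun = 80,
#'                       phosphate = 2.2, heart_failure = 0, diabetes = 1,
#'                       female = 0), params)
#' @export
dife_score <- function(input, params) {
  stopifnot(inherits(params, "dife_parameters"))
  input <- check_dife_input(input)
  w <- weighting_w(input, params)
  p <- unclass(params)
  core <- p[["p2"]] * input$scr^p[["p3"]] * log(input$age)^p[["p4"]] *
    input$alb^p[["p5"]] * input$hb^p[["p6"]] * log(input$bun)^p[["p7"]] *
    input$phosphate^p[["p8"]]
  y <- p[["p15"]] + p[["p1"]] * w *
    (core + p[["p9"]] * exp(input$heart_failure) +
       p[["p10"]] * exp(input$diabetes) + p[["p11"]] * exp(input$female) +
       p[["p16"]])
  if (any(!is.finite(y))) {
    stop_domain("non-finite score; check parameter magnitudes")
  }
  y
}

#' Classify initiation urgency at a score threshold
#'
#' Scores below the threshold predict poor 3-year survival and an immediate
#' start; scores at or above it predict good survival, so the patient can
#' prepare (e.g. vascular access placement) and wait. The boundary score is
#' assigned to the good side by default.
#'
#' @param score Numeric DIFE score(s).
#' @param threshold Decision threshold (default 30).
#' @param boundary_good If `TRUE` (default), a score exactly at the
#'   threshold maps to `prepare_and_wait`/`good`.
#' @return Data frame with columns `score`, `decision` (factor:
#'   `start_now`, `prepare_and_wait`) and `predicted_survival` (factor:
#'   `poor`, `good`).
#' @examples
#' classify_initiation(c(29.35, 42.16))
#' @export
classify_initiation <- function(score, threshold = 30, boundary_good = TRUE) {
  if (any(!is.finite(score)) || !is.finite(threshold)) {
    stop_domain("score and threshold must be finite")
  }
  good <- if (boundary_good) score >= threshold else score > threshold
  data.frame(
    score = score,
    decision = factor(ifelse(good, "prepare_and_wait", "start_now"),
                      levels = c("start_now", "prepare_and_wait")),
    predicted_survival = factor(ifelse(good, "good", "poor"),
                                levels = c("poor", "good"))
  )
}
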