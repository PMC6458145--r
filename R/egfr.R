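#' @title Estimated GFR calculators
#' @description The two creatinine-based eGFR equations used as conventional
#'   comparators for dialysis-initiation timing: the Chinese-modified MDRD
#'   study equation 7 and the 2009 CKD-EPI creatinine equation.
#' @name egfr
NULL

#' Chinese-modified MDRD study equation 7
#'
#' eGFR = 170 x Scr^-0.999 x age^-0.176 x BUN^-0.170 x Alb^0.318,
#' multiplied by 0.762 for women and by 1.202 for patients of Chinese
#' descent (the study-population default). Scr and BUN in mg/dL, Alb in
#' g/dL. The raw floating-point value is returned; round for display.
#'
#' @param scr Serum creatinine, mg/dL (> 0). Vectorized.
#' @param age Age in years (>= 18).
#' @param bun Blood urea nitrogen, mg/dL (> 0).
#' @param alb Serum albumin, g/dL (> 0).
#' @param female 0/1 (or logical) indicator.
#' @param chinese 0/1 (or logical) indicator; defaults to `TRUE`.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' round(egfr_cmdrd(scr = 6.6, age = 65, bun = 80, alb = 3.0,
#'                  female = 0))            # 10
#' @export
egfr_cmdrd <- function(scr, age, bun, alb, female, chinese = TRUE) {
  if (any(!is.finite(scr)) || any(scr <= 0) ||
      any(!is.finite(bun)) || any(bun <= 0) ||
      any(!is.finite(alb)) || any(alb <= 0)) {
    stop_domain("scr, bun and alb must be strictly positive")
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    stop_domain("age must be >= 18 years")
  }
  female <- as.numeric(female)
  chinese <- as.numeric(chinese)
  170 * scr^-0.999 * age^-0.176 * bun^-0.170 * alb^0.318 *
    ifelse(female == 1, 0.762, 1) * ifelse(chinese == 1, 1.202, 1)
}

#' CKD-EPI 2009 creatinine equation
#'
#' eGFR = 141 x min(Scr/k, 1)^a x max(Scr/k, 1)^-1.209 x 0.993^age
#' x 1.018 (if female), with k = 0.7 and a = -0.329 for women, k = 0.9 and
#' a = -0.411 for men. The 1.159 race coefficient of the 2009 publication
#' is off by default (`black = FALSE`).
#'
#' @param scr Serum creatinine, mg/dL (> 0). Vectorized.
#' @param age Age in years (>= 18).
#' @param female 0/1 (or logical) indicator.
#' @param black 0/1 (or logical); applies the 1.159 coefficient when 1.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_ckdepi <- function(scr, age, female, black = FALSE) {
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop_domain("scr must be strictly positive")
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    stop_domain("age must be >= 18 years")
  }
  female <- as.numeric(female)
  black <- as.numeric(black)
  kappa <- ifelse(female == 1, 0.7, 0.9)
  alpha <- ifelse(female == 1, -0.329, -0.411)
  r <- scr / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^-1.209 * 0.993^age *
    ifelse(female == 1, 1.018, 1) * ifelse(black == 1, 1.159, 1)
}
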