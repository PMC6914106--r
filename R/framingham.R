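# Sex-specific Cox coefficients of the Framingham general cardiovascular
# disease (CVD) 10-year risk functions (office-based lipid model).
.fram_coef <- list(
  male = list(
    ln_age = 3.06117, ln_tc = 1.12370, ln_hdl = -0.93263,
    ln_sbp_untreated = 1.93303, ln_sbp_treated = 1.99881,
    smoker = 0.65451, diabetes = 0.57367,
    mean_lp = 23.9802, s0_10 = 0.88936
  ),
  female = list(
    ln_age = 2.32888, ln_tc = 1.20904, ln_hdl = -0.70833,
    ln_sbp_untreated = 2.76157, ln_sbp_treated = 2.82263,
    smoker = 0.52873, diabetes = 0.69154,
    mean_lp = 26.1931, s0_10 = 0.95012
  )
)

#' Framingham 10-year general cardiovascular disease risk
#'
#' Sex-specific log-linear survival model on log-transformed continuous
#' covariates, with separate coefficients for treated and untreated systolic
#' blood pressure. Returns `1 - S0(10)^exp(lp - mean_lp)`.
#'
#' The equation is calibrated for ages 30-74; out-of-range continuous
#' covariates raise a warning and are clamped to the validity range when
#' `clamp = TRUE` (default), otherwise an error.
#'
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param sbp Systolic blood pressure, mm Hg.
#' @param bp_treated Logical: on antihypertensive treatment.
#' @param smoker Logical: current smoker.
#' @param diabetic Logical: diabetes present.
#' @param total_cholesterol Total cholesterol, mg/dL.
#' @param hdl_cholesterol HDL cholesterol, mg/dL.
#' @param clamp Clamp out-of-range covariates (with a warning) instead of
#'   erroring.
#' @return 10-year probability of a general CVD event, in \[0,1\].
#' @examples
#' framingham_gcvd_risk(61, "female", 124, bp_treated = FALSE, smoker = TRUE,
#'                      diabetic = FALSE, total_cholesterol = 180,
#'                      hdl_cholesterol = 47)
#' @export
framingham_gcvd_risk <- function(age, sex = c("male", "female"), sbp,
                                 bp_treated = FALSE, smoker = FALSE,
                                 diabetic = FALSE, total_cholesterol = 200,
                                 hdl_cholesterol = 50, clamp = TRUE) {
  sex <- match.arg(sex)
  cf <- .fram_coef[[sex]]
  rng <- function(x, lo, hi, what) {
    if (any(x < lo | x > hi)) {
      if (!clamp) stop(sprintf("%s outside validity range [%g, %g]",
                               what, lo, hi), call. = FALSE)
      warning(sprintf("%s clamped to [%g, %g]", what, lo, hi), call. = FALSE)
      x <- pmin(pmax(x, lo), hi)
    }
    x
  }
  age <- rng(age, 30, 74, "age")
  if (any(sbp <= 0) || any(total_cholesterol <= 0) || any(hdl_cholesterol <= 0)) {
    stop("pressures and lipids must be positive", call. = FALSE)
  }
  b_sbp <- ifelse(bp_treated, cf$ln_sbp_treated, cf$ln_sbp_untreated)
  lp <- cf$ln_age * log(age) + cf$ln_tc * log(total_cholesterol) +
    cf$ln_hdl * log(hdl_cholesterol) + b_sbp * log(sbp) +
    cf$smoker * as.numeric(smoker) + cf$diabetes * as.numeric(diabetic)
  1 - cf$s0_10^exp(lp - cf$mean_lp)
}

#' Convert between 10-year and annual event probabilities
#'
#' Constant-hazard conversion: `p1 = 1 - (1 - p10)^(1/10)` and its inverse.
#'
#' @param p10 10-year probability in \[0, 1).
#' @param p1 Annual probability in \[0, 1).
#' @return The converted probability.
#' @export
annual_from_10yr <- function(p10) {
  if (any(p10 < 0) || any(p10 >= 1)) stop("p10 must be in [0, 1)", call. = FALSE)
  1 - (1 - p10)^(1 / 10)
}

#' @rdname annual_from_10yr
#' @export
ten_year_from_annual <- function(p1) {
  if (any(p1 < 0) || any(p1 >= 1)) stop("p1 must be in [0, 1)", call. = FALSE)
  1 - (1 - p1)^10
}
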