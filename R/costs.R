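#' Annual medication cost for one category
#'
#' Category-gradient costing: `base * slope[category]`, with the category-2
#' cost additionally multiplied by `1 - unmedicated_fraction` (the share of
#' category-2 patients managed by the DTx alone, without pharmacologic
#' treatment).
#'
#' @param category Outcome category 1-4.
#' @param gradient List with `base` (USD/year) and `slopes` (4 multipliers).
#' @param unmedicated_fraction Fraction of category-2 patients off
#'   medications (0 for the TAU arm).
#' @return USD per year.
#' @export
medication_cost <- function(category, gradient, unmedicated_fraction = 0) {
  stopifnot(category %in% 1:4)
  f <- ifelse(category == 2, 1 - unmedicated_fraction, 1)
  gradient$base * gradient$slopes[category] * f
}

#' Annual comorbidity medication cost for one category
#'
#' Prevalence-weighted sum over comorbid drug classes; the patient's
#' primary-disease category indexes every comorbidity gradient (improvement
#' in the primary biomarker lowers comorbidity medication intensity too).
#'
#' @param category Outcome category 1-4.
#' @param comorbidity_prevalence Named prevalence vector.
#' @param gradients Named list of cost gradients (as in
#'   `params$med_costs`), one per comorbidity.
#' @return USD per year.
#' @export
comorbid_med_cost <- function(category, comorbidity_prevalence, gradients) {
  stopifnot(category %in% 1:4)
  total <- 0
  for (nm in names(comorbidity_prevalence)) {
    g <- gradients[[nm]]
    total <- total + comorbidity_prevalence[[nm]] * g$base * g$slopes[category]
  }
  total
}

#' Annual CVD event rate by HbA1c category (T2DM model)
#'
#' @param category Outcome category 1-4.
#' @param baseline_rate Reference annual event rate (events/person-year)
#'   multiplied by the category hazard ratio.
#' @param hazard_ratios 4 multipliers (base case 1/1/1.25/1.98).
#' @return Events per person-year.
#' @export
cvd_annual_rate_t2dm <- function(category, baseline_rate, hazard_ratios) {
  stopifnot(category %in% 1:4, baseline_rate >= 0)
  baseline_rate * hazard_ratios[category]
}

#' Per-category annual CVD event rates for a parameter set
#'
#' T2DM: baseline rate times the published hazard ratios. HTN: the
#' Framingham general-CVD 10-year risk of a representative profile per
#' category (age and smoking/diabetes/lipid mixture from the parameters,
#' SBP at the category representative value, treated except category 1),
#' averaged over sex, converted to an annual rate, and multiplied by the
#' calibrated `risk_scale`.
#'
#' @param params A `dtx_params` object.
#' @return Numeric length-4 vector of events/person-year.
#' @export
category_cvd_rates <- function(params) {
  cv <- params$cvd
  if (identical(cv$model, "hazard_ratio")) {
    return(cv$baseline_annual_rate * cv$hazard_ratios * cv$risk_scale)
  }
  fr <- cv$framingham
  sbp <- params$disease$rep_values
  rates <- vapply(1:4, function(k) {
    p10 <- 0
    for (sex in c("male", "female")) {
      wsex <- if (sex == "female") params$female_fraction else 1 - params$female_fraction
      for (sm in c(FALSE, TRUE)) {
        wsm <- if (sm) fr$smoker_fraction else 1 - fr$smoker_fraction
        for (db in c(FALSE, TRUE)) {
          wdb <- if (db) fr$diabetic_fraction else 1 - fr$diabetic_fraction
          p10 <- p10 + wsex * wsm * wdb * framingham_gcvd_risk(
            age = params$mean_age, sex = sex, sbp = sbp[k],
            bp_treated = fr$treated[k], smoker = sm, diabetic = db,
            total_cholesterol = fr$total_cholesterol,
            hdl_cholesterol = fr$hdl_cholesterol
          )
        }
      }
    }
    annual_from_10yr(p10)
  }, numeric(1))
  rates * cv$risk_scale
}

#' Prorate a year-1 saving for a benefit-realization delay
#'
#' Savings begin `delay_months` into year 1 and accrue linearly thereafter:
#' the year-1 amount is scaled by `(12 - delay_months)/12`; later years are
#' unscaled.
#'
#' @param undelayed_annual_saving USD (or any annual amount).
#' @param delay_months Months in \[0, 12\].
#' @param year Model year.
#' @return The prorated amount.
#' @export
apply_benefit_delay <- function(undelayed_annual_saving, delay_months, year) {
  stopifnot(delay_months >= 0, delay_months <= 12)
  if (year == 1) {
    undelayed_annual_saving * (12 - delay_months) / 12
  } else {
    undelayed_annual_saving
  }
}

#' Discount a value to present (year-1) terms
#'
#' @param value USD or QALYs accruing in `year`.
#' @param year Model year (1-based; year 1 is undiscounted).
#' @param rate Annual discount rate (base case 0.03).
#' @return Present value.
#' @export
discount <- function(value, year, rate) {
  stopifnot(rate >= 0)
  value / (1 + rate)^(year - 1)
}

# Per-category annual values used by both the cohort engine and the
# microsimulation: medication costs (TAU and DTx styles), CVD costs, and
# utilities. The DTx style differs from TAU only through the category-2
# unmedicated fraction.
state_values <- function(params) {
  f <- params$cat2_unmedicated_fraction
  primary <- params$med_costs[[params$primary_med]]
  dis_tau <- vapply(1:4, medication_cost, numeric(1), gradient = primary)
  dis_dtx <- vapply(1:4, medication_cost, numeric(1), gradient = primary,
                    unmedicated_fraction = f)
  com <- vapply(1:4, comorbid_med_cost, numeric(1),
                comorbidity_prevalence = params$comorbidity_prevalence,
                gradients = params$med_costs)
  rates <- category_cvd_rates(params)
  cvd_cost <- rates * params$cvd$event_cost
  u <- realized_utilities(params$utilities)
  u_tau <- c(u$cat1, u$cat2_meds, u$cat3, u$cat4)
  u_dtx <- c(u$cat1, f * u$cat2_no_meds + (1 - f) * u$cat2_meds, u$cat3, u$cat4)
  cvd_dis <- rates * params$utilities$cvd_event_inc
  list(
    disease_med = list(tau = dis_tau, dtx = dis_dtx),
    comorbid_med = com, cvd_rates = rates, cvd_cost = cvd_cost,
    utility = list(tau = u_tau, dtx = u_dtx), cvd_disutility = cvd_dis
  )
}

# Expected annual components for one occupancy segment, with the year-1
# benefit delay blending toward the average TAU year-1 state for delayed
# segments (equivalent to prorating the year-1 saving versus TAU by
# (12 - delay)/12).
segment_components <- function(seg, anchor, sv, delays) {
  style <- seg$style
  dmed <- sum(seg$dist * sv$disease_med[[style]])
  cmed <- sum(seg$dist * sv$comorbid_med)
  cvd <- sum(seg$dist * sv$cvd_cost)
  util <- sum(seg$dist * sv$utility[[style]])
  cvd_u <- sum(seg$dist * sv$cvd_disutility)
  if (isTRUE(seg$delayed)) {
    dm <- delays$medication_months / 12
    dc <- delays$cvd_months / 12
    dmed <- dm * sum(anchor * sv$disease_med$tau) + (1 - dm) * dmed
    cmed <- dm * sum(anchor * sv$comorbid_med) + (1 - dm) * cmed
    cvd <- dc * sum(anchor * sv$cvd_cost) + (1 - dc) * cvd
    util <- dm * sum(anchor * sv$utility$tau) + (1 - dm) * util
    cvd_u <- dc * sum(anchor * sv$cvd_disutility) + (1 - dc) * cvd_u
  }
  c(disease_med = dmed, comorbid_med = cmed, cvd_inpatient = cvd,
    utility = util, cvd_disutility = cvd_u)
}

#' Annual cost breakdown for one arm
#'
#' Converts a trajectory into per-year expected costs per enrollee, split
#' into primary-disease medications, comorbidity medications and CVD
#' inpatient costs, both undiscounted and discounted to present value. The
#' year-1 clinical-inertia delays gate when DTx-arm reductions begin;
#' withdrawal strata are costed at their return-rule category distributions.
#'
#' @param trajectory A `dtx_trajectory` (see [simulate_cohort()]).
#' @param params The `dtx_params` behind the trajectory.
#' @return A data.frame with one row per year: `arm`, `year`,
#'   `disease_med`, `comorbid_med`, `cvd_inpatient`, `total` (discounted),
#'   their `_undisc` counterparts, and `person_months` (12 per enrollee:
#'   the per-participant-per-month denominator counts all original
#'   enrollees).
#' @export
arm_costs <- function(trajectory, params) {
  sv <- state_values(params)
  rows <- lapply(1:3, function(y) {
    segs <- trajectory_segments(trajectory, y)
    comp <- c(disease_med = 0, comorbid_med = 0, cvd_inpatient = 0)
    for (seg in segs) {
      sc <- segment_components(seg, trajectory$tau_dist[[1]], sv, params$delays)
      comp <- comp + seg$mass * seg$frac *
        sc[c("disease_med", "comorbid_med", "cvd_inpatient")]
    }
    disc <- discount(comp, y, params$discount_rate)
    data.frame(
      arm = trajectory$arm, year = y,
      disease_med = disc[["disease_med"]],
      comorbid_med = disc[["comorbid_med"]],
      cvd_inpatient = disc[["cvd_inpatient"]],
      total = sum(disc),
      disease_med_undisc = comp[["disease_med"]],
      comorbid_med_undisc = comp[["comorbid_med"]],
      cvd_inpatient_undisc = comp[["cvd_inpatient"]],
      total_undisc = sum(comp),
      person_months = 12
    )
  })
  do.call(rbind, rows)
}

#' Per-participant-per-month savings
#'
#' Difference in total (discounted) cost between the TAU and DTx arms for a
#' year, divided by the per-enrollee person-month denominator (12: all
#' original enrollees count, including withdrawers).
#'
#' @param tau,dtx Cost breakdowns from [arm_costs()].
#' @param year Model year 1-3.
#' @param discounted Use discounted totals (default) or undiscounted.
#' @return USD per participant per month.
#' @export
pppm_savings <- function(tau, dtx, year, discounted = TRUE) {
  col <- if (discounted) "total" else "total_undisc"
  ty <- tau[tau$year == year, ]
  dy <- dtx[dtx$year == year, ]
  if (nrow(ty) != 1 || nrow(dy) != 1) stop("year not found", call. = FALSE)
  if (ty$person_months <= 0) stop("zero person-month denominator", call. = FALSE)
  (ty[[col]] - dy[[col]]) / ty$person_months
}
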