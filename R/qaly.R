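#' Health-state utility
#'
#' Utility of one model state: the category utility (with the
#' category-2 medication distinction), plus the CVD event decrement when an
#' event occurs in the year. Results are clamped to \[0, 1\].
#'
#' @param category Outcome category 1-4.
#' @param on_medications Logical; only affects category 2.
#' @param cvd_event Logical: a CVD event occurs in the year.
#' @param utilities The `utilities` component of a `dtx_params`.
#' @return Utility in \[0, 1\].
#' @examples
#' u <- default_parameters("T2DM")$utilities
#' state_utility(2, on_medications = FALSE, utilities = u)  # 0.82
#' state_utility(2, on_medications = TRUE, utilities = u)   # 0.80
#' @export
state_utility <- function(category, on_medications = TRUE, cvd_event = FALSE,
                          utilities) {
  stopifnot(category %in% 1:4)
  u <- realized_utilities(utilities)
  base <- switch(category, u$cat1,
                 if (on_medications) u$cat2_meds else u$cat2_no_meds,
                 u$cat3, u$cat4)
  if (cvd_event) base <- base + utilities$cvd_event_inc
  min(max(base, 0), 1)
}

#' Discounted QALYs per enrollee for one arm
#'
#' Sums discounted expected utility over the 3 years, weighting active and
#' withdrawn strata by occupancy and medication status, with the year-1
#' delays gating when the DTx arm's medication-status and CVD-risk utility
#' gains begin. CVD event disutility is applied in expectation as
#' rate x decrement within the event year.
#'
#' @param trajectory A `dtx_trajectory`.
#' @param params The `dtx_params` behind the trajectory.
#' @return Discounted QALYs per enrollee over the horizon.
#' @export
arm_qalys <- function(trajectory, params) {
  sv <- state_values(params)
  total <- 0
  for (y in 1:3) {
    uy <- 0
    for (seg in trajectory_segments(trajectory, y)) {
      sc <- segment_components(seg, trajectory$tau_dist[[1]], sv, params$delays)
      uy <- uy + seg$mass * seg$frac * (sc[["utility"]] + sc[["cvd_disutility"]])
    }
    total <- total + discount(uy, y, params$discount_rate)
  }
  total
}

#' Incremental cost-effectiveness result
#'
#' Computes the incremental discounted HRU savings and QALYs of DTx+TAU
#' versus TAU alone and the affine break-even program-cost function:
#' `breakeven(WTP) = delta_savings + WTP * delta_qaly`. The intervention is
#' cost effective at total 3-year program cost C and willingness-to-pay
#' lambda iff `C <= breakeven(lambda)` (program cost treated as an upfront
#' total).
#'
#' @param tau_costs,dtx_costs Cost breakdowns from [arm_costs()].
#' @param tau_qalys,dtx_qalys Discounted per-enrollee QALYs from
#'   [arm_qalys()].
#' @return A list of class `dtx_cea` with `delta_savings` (USD, discounted
#'   HRU savings per enrollee over 3 years), `delta_qaly`, and `breakeven`
#'   (a function of WTP).
#' @export
incremental <- function(tau_costs, dtx_costs, tau_qalys, dtx_qalys) {
  ds <- sum(tau_costs$total) - sum(dtx_costs$total)
  dq <- dtx_qalys - tau_qalys
  out <- list(
    delta_savings = ds,
    delta_qaly = dq,
    breakeven = function(wtp) ds + wtp * dq
  )
  class(out) <- "dtx_cea"
  out
}

#' Threshold curve of break-even program cost against willingness-to-pay
#'
#' @param result A `dtx_cea` from [incremental()].
#' @param wtp_grid Willingness-to-pay grid (USD/QALY); default 0 to 150,000
#'   in steps of 10,000.
#' @return data.frame with columns `wtp` and `breakeven_cost`.
#' @export
threshold_curve <- function(result, wtp_grid = seq(0, 150000, by = 10000)) {
  if (length(wtp_grid) == 0) stop("wtp_grid must be non-empty", call. = FALSE)
  data.frame(wtp = wtp_grid, breakeven_cost = result$breakeven(wtp_grid))
}

#' Run the full model for one parameter set
#'
#' Simulates both arms, computes cost breakdowns, QALYs, PPPM savings by
#' year and the incremental CEA result. This is the single entry point used
#' by the sensitivity analysis, the scenarios and the reports.
#'
#' @param params A validated `dtx_params` object.
#' @return A list of class `dtx_run` with `params`, `tau`/`dtx`
#'   trajectories, `tau_costs`/`dtx_costs`, `tau_qalys`/`dtx_qalys`,
#'   `pppm` (named vector: years 1-3 and the 3-year average, discounted) and
#'   `cea`.
#' @export
run_model <- function(params) {
  validate_parameters(params)
  tau <- simulate_cohort(params, "TAU")
  dtx <- simulate_cohort(params, "DTX_TAU")
  tau_costs <- arm_costs(tau, params)
  dtx_costs <- arm_costs(dtx, params)
  tau_q <- arm_qalys(tau, params)
  dtx_q <- arm_qalys(dtx, params)
  pppm <- vapply(1:3, function(y) pppm_savings(tau_costs, dtx_costs, y),
                 numeric(1))
  out <- list(
    params = params, tau = tau, dtx = dtx,
    tau_costs = tau_costs, dtx_costs = dtx_costs,
    tau_qalys = tau_q, dtx_qalys = dtx_q,
    pppm = c(y1 = pppm[1], y2 = pppm[2], y3 = pppm[3], avg = mean(pppm)),
    cea = incremental(tau_costs, dtx_costs, tau_q, dtx_q)
  )
  class(out) <- "dtx_run"
  out
}

#' @export
print.dtx_run <- function(x, ...) {
  cat(sprintf("<dtx_run> %s model\n", x$params$disease$id))
  cat(sprintf("  PPPM savings (discounted): y1 $%.0f, y2 $%.0f, y3 $%.0f (avg $%.0f)\n",
              x$pppm["y1"], x$pppm["y2"], x$pppm["y3"], x$pppm["avg"]))
  cat(sprintf("  3-year HRU savings: $%.0f/enrollee; incremental QALYs: %.4f\n",
              x$cea$delta_savings, x$cea$delta_qaly))
  cat(sprintf("  break-even program cost: $%.0f at $50k/QALY, $%.0f at $100k/QALY\n",
              x$cea$breakeven(50000), x$cea$breakeven(100000)))
  invisible(x)
}
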