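test_that("state utilities chain from the category-2 anchor", {
  u <- default_parameters("T2DM")$utilities
  expect_equal(state_utility(2, on_medications = FALSE, utilities = u), 0.82)
  expect_equal(state_utility(2, on_medications = TRUE, utilities = u), 0.80)
  expect_equal(state_utility(1, utilities = u), 0.84)
  # cumulative mode: increments accumulate toward worse states
  expect_equal(state_utility(3, utilities = u), 0.82 - 0.02 - 0.035)
  expect_equal(state_utility(4, utilities = u), 0.82 - 0.02 - 0.035 - 0.025)
  # a CVD event costs 0.1 in the event year, in any state
  for (k in 1:4) {
    expect_equal(state_utility(k, utilities = u) -
                   state_utility(k, cvd_event = TRUE, utilities = u), 0.1)
  }
  # absolute mode measures every increment from the anchor
  u2 <- u
  u2$increment_mode <- "absolute"
  expect_equal(state_utility(3, utilities = u2), 0.82 - 0.035)
})

test_that("equal utilities in every state give the closed-form discounted QALYs", {
  p <- default_parameters("T2DM")
  p$utilities$cat1_inc <- 0
  p$utilities$cat2_meds_inc <- 0
  p$utilities$cat3_inc <- 0
  p$utilities$cat4_inc <- 0
  p$utilities$cvd_event_inc <- 0
  p$cat2_unmedicated_fraction <- 0 # med status must not matter either
  u <- p$utilities$anchor
  expected <- u * (1 + 1 / 1.03 + 1 / 1.03^2)
  for (arm in c("TAU", "DTX_TAU")) {
    expect_equal(arm_qalys(simulate_cohort(p, arm), p), expected,
                 tolerance = 1e-10)
  }
})

test_that("raising a category utility increment weakly raises QALYs", {
  p <- default_parameters("T2DM")
  q0 <- arm_qalys(simulate_cohort(p, "DTX_TAU"), p)
  p2 <- p
  p2$utilities$cat1_inc <- p$utilities$cat1_inc + 0.01
  expect_gt(arm_qalys(simulate_cohort(p2, "DTX_TAU"), p2), q0)
})

test_that("the break-even function is affine with slope equal to incremental QALYs", {
  for (d in c("T2DM", "HTN")) {
    run <- base_run(d)
    cea <- run$cea
    # slope to machine precision
    expect_equal((cea$breakeven(100000) - cea$breakeven(50000)) / 50000,
                 cea$delta_qaly, tolerance = 1e-12)
    # intercept = total discounted HRU savings per enrollee
    expect_equal(cea$breakeven(0), cea$delta_savings, tolerance = 1e-12)
    expect_equal(cea$delta_savings,
                 sum(run$tau_costs$total) - sum(run$dtx_costs$total))
    # two grid points determine the whole tabulated line
    curve <- threshold_curve(cea, c(0, 25000, 50000, 125000))
    slope <- (curve$breakeven_cost[2] - curve$breakeven_cost[1]) / 25000
    expect_equal(curve$breakeven_cost,
                 curve$breakeven_cost[1] + slope * curve$wtp)
    expect_error(threshold_curve(cea, numeric(0)), "non-empty")
  }
})

test_that("a zero-effect intervention breaks even only at zero program cost", {
  p <- default_parameters("T2DM")
  P <- tau_transition_matrix(p$tau_persistence)
  p$attrition[c("y1_early", "y1_late", "y2", "y3")] <- 0
  p$cat2_unmedicated_fraction <- 0
  tau <- simulate_cohort(p, "TAU")
  dtx <- simulate_cohort(p, "DTX_TAU", tables = list(dtx = list(P, P, P)))
  cea <- incremental(arm_costs(tau, p), arm_costs(dtx, p),
                     arm_qalys(tau, p), arm_qalys(dtx, p))
  for (wtp in c(0, 50000, 150000)) {
    expect_equal(cea$breakeven(wtp), 0, tolerance = 1e-9)
  }
})

test_that("discount-rate ordering: 0% >= 3% >= 5% totals when savings are positive", {
  for (d in c("T2DM", "HTN")) {
    p <- default_parameters(d)
    tot <- function(rate) {
      p$discount_rate <- rate
      run_model(p)$cea$delta_savings
    }
    s0 <- tot(0); s3 <- tot(0.03); s5 <- tot(0.05)
    expect_gt(s3, 0)
    expect_true(s0 >= s3 && s3 >= s5)
  }
})
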