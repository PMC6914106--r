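test_that("category-gradient medication costs compose base, slope and deprescribing", {
  p <- default_parameters("T2DM")
  g <- p$med_costs$T2DM
  expect_equal(medication_cost(1, g), 0)                    # slope 0
  expect_equal(medication_cost(4, g), 2466 * 2.2)           # 5425.20
  expect_equal(medication_cost(2, g, unmedicated_fraction = 0.25),
               2466 * 0.33 * 0.75)
  # comorbidity costs: prevalence-weighted, indexed by the primary category
  expect_equal(
    comorbid_med_cost(3, p$comorbidity_prevalence, p$med_costs),
    0.60 * 775 * 1.5 + 0.60 * 1557 * 0.9
  )
  expect_equal(comorbid_med_cost(3, c(HC = 0), p$med_costs), 0)
})

test_that("T2DM CVD rates scale the baseline by the category hazard ratio", {
  hr <- c(1, 1, 1.25, 1.98)
  expect_equal(cvd_annual_rate_t2dm(1, 0.02, hr), cvd_annual_rate_t2dm(2, 0.02, hr))
  expect_equal(cvd_annual_rate_t2dm(4, 0.02, hr), 0.02 * 1.98)
  expect_equal(cvd_annual_rate_t2dm(3, 0, hr), 0)
})

test_that("Framingham risk matches the published worked example and is monotone", {
  # worked example of the source publication: 61-year-old woman, TC 180,
  # HDL 47, untreated SBP 124, smoker, not diabetic -> 10-year risk 10.48%
  r <- framingham_gcvd_risk(61, "female", 124, bp_treated = FALSE,
                            smoker = TRUE, diabetic = FALSE,
                            total_cholesterol = 180, hdl_cholesterol = 47)
  expect_equal(r, 0.1048, tolerance = 1e-3)
  # a profile at the risk-factor means has risk 1 - S0(10)
  expect_equal(framingham_gcvd_risk(61, "female", 125, FALSE, FALSE, FALSE,
                                    200, 50) <
                 framingham_gcvd_risk(61, "female", 155, FALSE, FALSE, FALSE,
                                      200, 50), TRUE)
  # positive diabetes and smoking coefficients
  base <- framingham_gcvd_risk(50, "male", 130, TRUE, FALSE, FALSE)
  expect_gt(framingham_gcvd_risk(50, "male", 130, TRUE, FALSE, TRUE), base)
  expect_gt(framingham_gcvd_risk(50, "male", 130, TRUE, TRUE, FALSE), base)
  # SBP monotonicity across a grid
  sbp <- seq(100, 180, by = 10)
  risks <- vapply(sbp, function(s)
    framingham_gcvd_risk(50, "female", s, TRUE, FALSE, FALSE), numeric(1))
  expect_true(all(diff(risks) > 0))
  expect_warning(framingham_gcvd_risk(80, "male", 130), "clamped")
  expect_error(framingham_gcvd_risk(80, "male", 130, clamp = FALSE), "range")
})

test_that("annual/10-year probability conversion is a consistent constant-hazard map", {
  expect_equal(annual_from_10yr(0), 0)
  expect_equal(annual_from_10yr(0.4), 1 - 0.6^0.1)
  p10 <- c(0.05, 0.2, 0.6, 0.95)
  expect_equal(ten_year_from_annual(annual_from_10yr(p10)), p10,
               tolerance = 1e-12)
  expect_error(annual_from_10yr(1), "p10")
})

test_that("benefit-delay proration and discounting follow their closed forms", {
  expect_equal(apply_benefit_delay(1000, 12, 1), 0)
  expect_equal(apply_benefit_delay(1000, 6, 1), 500)
  expect_equal(apply_benefit_delay(1000, 6, 2), 1000)
  expect_equal(discount(100, 3, 0.03), 100 / 1.03^2)
  expect_equal(discount(100, 1, 0.03), 100)
  expect_equal(discount(100, 3, 0), 100)
})

test_that("arm cost breakdowns respond linearly and respect discounting", {
  p <- default_parameters("T2DM")
  run <- base_run("T2DM")
  # doubling the CVD event cost doubles only the inpatient component
  p2 <- p
  p2$cvd$event_cost <- 2 * p$cvd$event_cost
  c2 <- arm_costs(simulate_cohort(p2, "DTX_TAU"), p2)
  expect_equal(c2$cvd_inpatient, 2 * run$dtx_costs$cvd_inpatient,
               tolerance = 1e-12)
  expect_equal(c2$disease_med, run$dtx_costs$disease_med, tolerance = 1e-12)
  # discounted totals never exceed undiscounted ones after year 1
  for (cc in list(run$tau_costs, run$dtx_costs)) {
    expect_true(all(cc$total[cc$year > 1] < cc$total_undisc[cc$year > 1]))
    expect_true(all(cc$total >= 0))
  }
})

test_that("savings rise with base medication cost and fall with longer delays", {
  p <- default_parameters("T2DM")
  y1 <- function(q) model_outcome(q, "pppm_y1")
  base <- y1(p)
  richer <- p
  richer$med_costs$T2DM$base <- p$med_costs$T2DM$base * 1.5
  expect_gt(y1(richer), base)
  slower <- p
  slower$delays$medication_months <- 9
  expect_lt(y1(slower), base)
  # years 2-3 are invariant to the medication delay
  expect_equal(model_outcome(slower, "pppm_y2"), model_outcome(p, "pppm_y2"),
               tolerance = 1e-10)
  expect_equal(model_outcome(slower, "pppm_y3"), model_outcome(p, "pppm_y3"),
               tolerance = 1e-10)
})

test_that("flat gradients and unit hazard ratios force zero incremental cost", {
  p <- default_parameters("T2DM")
  for (nm in names(p$med_costs)) p$med_costs[[nm]]$slopes <- rep(1, 4)
  p$cvd$hazard_ratios <- rep(1, 4)
  p$cat2_unmedicated_fraction <- 0 # no deprescribing channel either
  run <- run_model(p)
  expect_equal(unname(run$pppm[c("y1", "y2", "y3")]), rep(0, 3),
               tolerance = 1e-10)
})
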