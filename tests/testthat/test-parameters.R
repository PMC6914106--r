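test_that("base-case defaults carry the published inputs for both diseases", {
  t2 <- default_parameters("T2DM")
  ht <- default_parameters("HTN")

  expect_equal(t2$disease$category_bounds, c(6.5, 7.5, 9.0))
  expect_equal(ht$disease$category_bounds, c(120, 130, 140))
  expect_equal(t2$med_costs$T2DM$base, 2466)
  expect_equal(t2$med_costs$T2DM$slopes, c(0, 0.33, 1.2, 2.2))
  expect_equal(t2$med_costs$HC$base, 775)
  expect_equal(t2$med_costs$HC$slopes, c(0.5, 0.8, 1.5, 2))
  expect_equal(t2$med_costs$HTN$base, 1557)
  expect_equal(ht$med_costs$HTN$slopes, c(0, 0.15, 0.9, 1.8))
  expect_equal(t2$enrollment, c(0, 0.47, 0.34, 0.19))
  expect_equal(ht$enrollment, c(0, 0.37, 0.19, 0.44))
  expect_equal(t2$comorbidity_prevalence, c(HC = 0.60, HTN = 0.60))
  expect_equal(ht$comorbidity_prevalence, c(T2DM = 0.33))
  expect_equal(t2$effectiveness$responder_fraction_y1, 0.62)
  expect_equal(ht$effectiveness$responder_fraction_y1, 0.87)
  expect_equal(t2$effectiveness$mean_change_y1, -0.8)
  expect_equal(ht$effectiveness$mean_change_y1, -11)
  expect_equal(t2$cvd$event_cost, 116423)
  expect_equal(t2$cvd$hazard_ratios, c(1, 1, 1.25, 1.98))
  expect_equal(t2$utilities$anchor, 0.82)
  expect_equal(ht$utilities$anchor, 0.83)
  expect_equal(ht$utilities$cat4_inc, 0)
  expect_equal(t2$delays, list(medication_months = 6, cvd_months = 3))
  expect_equal(t2$discount_rate, 0.03)
  expect_equal(t2$cat2_unmedicated_fraction, 0.25)

  # defaults pass their own validation
  expect_silent(validate_parameters(t2))
  expect_silent(validate_parameters(ht))
})

test_that("validation rejects structurally invalid parameter sets", {
  p <- default_parameters("T2DM")

  bad <- p
  bad$enrollment <- c(0, 0.4, 0.3, 0.2) # sums to 0.9
  expect_error(validate_parameters(bad), "enrollment")

  bad <- p
  bad$enrollment <- c(0.1, 0.4, 0.3, 0.2) # category-1 mass at enrollment
  expect_error(validate_parameters(bad), "category-1")

  bad <- p
  bad$med_costs$T2DM$slopes <- c(0.5, 0.33, 1.2, 2.2) # decreasing
  expect_error(validate_parameters(bad), "slopes")

  bad <- p
  bad$discount_rate <- 0.08
  expect_error(validate_parameters(bad), "discount_rate")

  bad <- p
  bad$transition_tables <- list(dtx = list(diag(4) * 0.5, diag(4), diag(4)))
  expect_error(validate_parameters(bad), "not stochastic.*row")
})

test_that("sensitivity bounds honor the published asymmetric ranges", {
  p <- default_parameters("T2DM")

  lo <- apply_sa_bound(p, "mean_improvement", "low")
  expect_equal(lo$effectiveness$mean_change_y1, -0.8 * 0.6) # -40%
  expect_equal(lo$effectiveness$responder_fraction_y1, 0.62 * 0.6)
  hi <- apply_sa_bound(p, "mean_improvement", "high")
  expect_equal(hi$effectiveness$mean_change_y1, -0.8 * 1.2) # +20%

  expect_equal(apply_sa_bound(p, "discount_rate", "high")$discount_rate, 0.05)
  expect_equal(apply_sa_bound(p, "discount_rate", "low")$discount_rate, 0)
  expect_equal(
    apply_sa_bound(p, "cat2_unmedicated_fraction", "low")$cat2_unmedicated_fraction,
    0
  )
  expect_equal(
    apply_sa_bound(p, "comorbid_HC_prevalence", "low")$comorbidity_prevalence[["HC"]],
    0.6 * 0.7
  )
  expect_equal(
    apply_sa_bound(p, "comorbid_HC_prevalence", "high")$comorbidity_prevalence[["HC"]],
    0.6 * 1.1
  )
  expect_equal(
    apply_sa_bound(p, "T2DM_med_gradient", "high")$med_costs$T2DM$slopes,
    c(0, 0.33, 1.2, 2.2) * 1.1
  )
  expect_error(apply_sa_bound(p, "no_such_parameter", "low"), "unknown")

  # symmetric ranges are equidistant from base
  reg <- sa_registry(p)
  sym <- reg[reg$printed_range %in% c("+/-20%", "+/-10%", "+/-5", "+/-3", "+/-1"), ]
  expect_gt(nrow(sym), 5)
  expect_equal(sym$base - sym$sa_low, sym$sa_high - sym$base, tolerance = 1e-12)

  # bound application is pure: base object untouched
  expect_equal(p$discount_rate, 0.03)
})

test_that("YAML serialization round-trips the full parameter set", {
  for (d in c("T2DM", "HTN")) {
    p <- default_parameters(d)
    txt <- write_parameters(p)
    q <- load_parameters(txt)
    expect_equal(q$enrollment, p$enrollment, tolerance = 1e-10)
    expect_equal(q$med_costs, p$med_costs, tolerance = 1e-10)
    expect_equal(q$utilities, p$utilities, tolerance = 1e-10)
    expect_equal(q$effectiveness, p$effectiveness, tolerance = 1e-10)
    # NULL-valued optional fields (e.g. hazard ratios in the Framingham
    # model) may be dropped by the mapping format; all set fields survive
    expect_equal(q$cvd[names(q$cvd)], p$cvd[names(q$cvd)], tolerance = 1e-10)
    expect_setequal(names(p$cvd)[!vapply(p$cvd, is.null, logical(1))],
                    names(q$cvd))
    expect_equal(q$comorbidity_prevalence, p$comorbidity_prevalence,
                 tolerance = 1e-10)
    expect_equal(q$attrition, p$attrition, tolerance = 1e-10)
    expect_equal(q$disease$rep_values, p$disease$rep_values, tolerance = 1e-10)
  }

  # file round-trip, including attached transition tables
  p <- default_parameters("HTN")
  p$transition_tables <- synthesize_transition_tables(p)[c("dtx", "tau")]
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  q <- load_parameters(f)
  expect_equal(q$transition_tables$dtx, p$transition_tables$dtx,
               tolerance = 1e-10)
})

test_that("config overrides apply and invalid configs fail with named fields", {
  p <- default_parameters("T2DM")
  txt <- write_parameters(p)
  override <- sub("discount_rate: 0.03", "discount_rate: 0.0", txt, fixed = TRUE)
  q <- load_parameters(override)
  expect_equal(q$discount_rate, 0)
  expect_equal(q$med_costs$T2DM$base, 2466) # everything else at base

  bad <- sub("- 0.47", "- 0.37", txt, fixed = TRUE) # enrollment sums to 0.9
  expect_error(load_parameters(bad), "enrollment")

  # missing keys fall back to base with a notice
  expect_message(load_parameters("disease:\n  id: HTN\n"), "base case")
})

test_that("parameter registry exports name/base/bounds/units", {
  reg <- parameter_registry(default_parameters("HTN"))
  expect_true(all(c("name", "units", "base", "sa_low", "sa_high") %in% names(reg)))
  expect_true("comorbid_T2DM_prevalence" %in% reg$name)
  expect_false("cvd_hazard_ratios" %in% reg$name) # HTN uses Framingham
  f <- withr::local_tempfile(fileext = ".csv")
  parameter_registry(default_parameters("HTN"), f)
  expect_true(file.exists(f))
})
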