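test_that("biomarker classification follows the printed interval conventions", {
  t2 <- disease_model("T2DM")
  ht <- disease_model("HTN")
  expect_identical(classify_biomarker(t2, c(6.4, 6.5, 7.49, 7.5, 9.0, 9.01)),
                   c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_identical(classify_biomarker(ht, c(119.9, 120, 129.9, 130, 139.9, 140)),
                   c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_error(classify_biomarker(t2, NaN), "finite")
  expect_error(classify_biomarker(t2, -1), "finite")
})

test_that("TAU transition keeps persistence mass and spills symmetrically", {
  expect_equal(tau_transition(c(0, 1, 0, 0), 0.8), c(0.1, 0.8, 0.1, 0))
  # boundary categories reflect inward
  expect_equal(tau_transition(c(1, 0, 0, 0), 0.8), c(0.8, 0.2, 0, 0))
  expect_equal(tau_transition(c(0, 0, 0, 1), 0.8), c(0, 0, 0.2, 0.8))
  # persistence 1 is the identity
  d <- c(0.2, 0.3, 0.4, 0.1)
  expect_equal(tau_transition(d, 1), d)
  # conservation for arbitrary distributions
  set.seed(42)
  for (i in 1:25) {
    d <- random_distribution()
    expect_equal(sum(tau_transition(d, stats::runif(1))), 1, tolerance = 1e-12)
  }
})

test_that("DTx transition is the matrix product and validates its rows", {
  p <- default_parameters("T2DM")
  tt <- synthesize_transition_tables(p)
  d <- p$enrollment
  expect_equal(dtx_transition(d, 1, tt), as.numeric(d %*% tt$dtx[[1]]))
  ident <- list(dtx = list(diag(4)))
  expect_equal(dtx_transition(d, 1, ident), d)
  expect_error(dtx_transition(d, 7, tt), "year")
  bad <- list(dtx = list(matrix(0.5, 4, 4)))
  expect_error(dtx_transition(d, 1, bad), "stochastic")
})

test_that("attrition arithmetic reproduces the printed schedule", {
  p <- default_parameters("T2DM")
  att <- attrition_masses(p$attrition)
  expect_equal(att$retained, c(0.64, 0.576, 0.5184))
  # 36% of enrollees withdraw by the end of year 1
  expect_equal(att$strata$w_early + att$strata$w_y1_late, 0.36)
  # zero attrition leaves everyone active
  none <- p$attrition
  none[c("y1_early", "y1_late", "y2", "y3")] <- 0
  expect_equal(attrition_masses(none)$retained, c(1, 1, 1))
})

test_that("cohort mass is conserved every year in both arms", {
  set.seed(7)
  for (d in c("T2DM", "HTN")) {
    for (seed in 1:5) {
      p <- random_parameter_set(d, seed)
      for (arm in c("TAU", "DTX_TAU")) {
        tr <- simulate_cohort(p, arm)
        for (y in 1:3) expect_equal(cohort_mass(tr, y), 1, tolerance = 1e-9)
        for (y in 1:3) expect_equal(sum(tr$active_dist[[y]]), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("TAU year-1 distribution composes the persistence transition", {
  p <- default_parameters("T2DM")
  tr <- simulate_cohort(p, "TAU")
  expect_equal(tr$active_dist[[1]],
               tau_transition(p$enrollment, p$tau_persistence))
  expect_equal(tr$retained, c(1, 1, 1))
})

test_that("identical tables across arms give identical trajectories and zero increments", {
  p <- default_parameters("T2DM")
  P <- tau_transition_matrix(p$tau_persistence)
  null_tables <- list(dtx = list(P, P, P), tau = list(P, P, P))
  # no attrition and no category-2 deprescribing: the arms collapse
  p$attrition[c("y1_early", "y1_late", "y2", "y3")] <- 0
  p$cat2_unmedicated_fraction <- 0
  dtx <- simulate_cohort(p, "DTX_TAU", tables = null_tables)
  tau <- simulate_cohort(p, "TAU")
  for (y in 1:3) expect_equal(dtx$active_dist[[y]], tau$active_dist[[y]])
  dtx_c <- arm_costs(dtx, p)
  tau_c <- arm_costs(tau, p)
  for (y in 1:3) expect_equal(pppm_savings(tau_c, dtx_c, y), 0, tolerance = 1e-10)
  expect_equal(arm_qalys(dtx, p), arm_qalys(tau, p), tolerance = 1e-12)
})

test_that("earlier year-1 attrition weakly lowers every later retained fraction", {
  p <- default_parameters("T2DM")
  base <- attrition_masses(p$attrition)$retained
  p$attrition$y1_early <- 0.35
  more <- attrition_masses(p$attrition)$retained
  expect_true(all(more <= base))
})
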