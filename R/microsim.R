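# Sample next categories for a vector of current categories under a
# row-stochastic matrix.
sample_transition <- function(current, M) {
  out <- integer(length(current))
  u <- stats::runif(length(current))
  for (k in 1:4) {
    idx <- which(current == k)
    if (length(idx) == 0) next
    cum <- cumsum(M[k, ])
    out[idx] <- findInterval(u[idx], cum, left.open = TRUE) + 1L
  }
  out
}

sample_distribution <- function(n, dist) {
  findInterval(stats::runif(n), cumsum(dist), left.open = TRUE) + 1L
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_patients` individual trajectories per arm by sampling
#' category paths from the same transition rows, attrition events from the
#' same schedule, and return-rule categories from the TAU-arm
#' distributions, then accumulates per-patient costs and QALYs with rules
#' identical to the deterministic cohort engine (same clinical-inertia
#' delay blending, same discounting). Its aggregates converge to the
#' deterministic [run_model()] output and serve as the brute-force
#' validation oracle of the cohort engine.
#'
#' @param params A validated `dtx_params` object.
#' @param n_patients Number of simulated patients per arm.
#' @param seed Integer seed (single pseudo-random stream per run).
#' @return A list with `n`, `seed`, empirical `retained` fractions (end of
#'   each year, DTx arm), `active_dist_y1` (empirical year-1 distribution of
#'   the post-month-3 DTx pool), per-arm mean discounted 3-year `cost` and
#'   `qaly` with standard errors, `pppm` (empirical per-year savings per
#'   participant per month, discounted) and `pppm_se`.
#' @export
microsimulate <- function(params, n_patients, seed) {
  stopifnot(n_patients >= 1)
  validate_parameters(params)
  set.seed(seed)
  n <- as.integer(n_patients)
  sv <- state_values(params)
  tables <- params$transition_tables
  if (is.null(tables)) tables <- synthesize_transition_tables(params)
  P <- tau_transition_matrix(params$tau_persistence)
  # TAU-arm average distributions anchor the year-1 delay blend and the
  # year-2/3 return-to-average-TAU rule
  tau_ref <- simulate_cohort(params, "TAU")$tau_dist
  a <- params$attrition
  dm <- params$delays$medication_months / 12
  dc <- params$delays$cvd_months / 12
  disc <- (1 + params$discount_rate)^-(0:2)

  med_tau <- sv$disease_med$tau + sv$comorbid_med
  med_dtx <- sv$disease_med$dtx + sv$comorbid_med
  cvd <- sv$cvd_cost
  u_tau <- sv$utility$tau + sv$cvd_disutility
  u_dtx <- sv$utility$dtx + sv$cvd_disutility
  # utility split needed for the differing med/CVD delay blends in year 1
  u_tau_state <- sv$utility$tau
  u_dtx_state <- sv$utility$dtx
  cvd_dis <- sv$cvd_disutility

  k0 <- sample_distribution(n, params$enrollment)

  # --- TAU arm ---
  tau_cost <- matrix(0, n, 3)
  tau_util <- matrix(0, n, 3)
  kt <- k0
  for (y in 1:3) {
    kt <- sample_transition(kt, P)
    tau_cost[, y] <- (med_tau[kt] + cvd[kt]) * disc[y]
    tau_util[, y] <- u_tau[kt] * disc[y]
  }

  # --- DTx arm ---
  early <- stats::runif(n) < a$y1_early
  k1 <- sample_transition(k0, tables$dtx[[1]])
  late <- !early & (stats::runif(n) < a$y1_late)
  active1 <- !early & !late
  w2 <- active1 & (stats::runif(n) < a$y2)
  active2 <- active1 & !w2
  w3 <- active2 & (stats::runif(n) < a$y3)
  k2 <- sample_transition(k1, tables$dtx[[2]])
  k3 <- sample_transition(k2, tables$dtx[[3]])
  j1 <- sample_distribution(n, tau_ref[[1]])
  j2 <- sample_distribution(n, tau_ref[[2]])
  j3 <- sample_distribution(n, tau_ref[[3]])

  dtx_cost <- matrix(0, n, 3)
  dtx_util <- matrix(0, n, 3)

  # year 1: early withdrawers accrue enrollment-state TAU-style outcomes;
  # the remaining pool accrues average-TAU-state outcomes for the delay
  # months and its year-1 DTx state thereafter
  c1 <- ifelse(early, med_tau[k0] + cvd[k0],
               dm * med_tau[j1] + (1 - dm) * med_dtx[k1] +
                 dc * cvd[j1] + (1 - dc) * cvd[k1])
  u1 <- ifelse(early, u_tau_state[k0] + cvd_dis[k0],
               dm * u_tau_state[j1] + (1 - dm) * u_dtx_state[k1] +
                 dc * cvd_dis[j1] + (1 - dc) * cvd_dis[k1])
  dtx_cost[, 1] <- c1
  dtx_util[, 1] <- u1

  # year 2
  c2 <- (med_tau[k0] + cvd[k0]) * (early | late) +
    0.5 * ((med_dtx[k2] + cvd[k2]) + (med_tau[j2] + cvd[j2])) * w2 +
    (med_dtx[k2] + cvd[k2]) * active2
  u2 <- u_tau[k0] * (early | late) +
    0.5 * (u_dtx[k2] + u_tau[j2]) * w2 +
    u_dtx[k2] * active2
  dtx_cost[, 2] <- c2 * disc[2]
  dtx_util[, 2] <- u2 * disc[2]

  # year 3
  active3 <- active2 & !w3
  c3 <- (med_tau[k0] + cvd[k0]) * (early | late) +
    (med_tau[j3] + cvd[j3]) * w2 +
    0.5 * ((med_dtx[k3] + cvd[k3]) + (med_tau[j3] + cvd[j3])) * w3 +
    (med_dtx[k3] + cvd[k3]) * active3
  u3 <- u_tau[k0] * (early | late) +
    u_tau[j3] * w2 +
    0.5 * (u_dtx[k3] + u_tau[j3]) * w3 +
    u_dtx[k3] * active3
  dtx_cost[, 3] <- c3 * disc[3]
  dtx_util[, 3] <- u3 * disc[3]

  se <- function(x) stats::sd(x) / sqrt(length(x))
  tau_total <- rowSums(tau_cost)
  dtx_total <- rowSums(dtx_cost)
  pppm <- vapply(1:3, function(y) {
    mean(tau_cost[, y] - dtx_cost[, y]) / 12
  }, numeric(1))
  pppm_se <- vapply(1:3, function(y) {
    sqrt(se(tau_cost[, y])^2 + se(dtx_cost[, y])^2) / 12
  }, numeric(1))

  pool <- !early
  list(
    n = n, seed = seed,
    retained = c(mean(active1), mean(active2), mean(active3)),
    retained_se = c(se(active1), se(active2), se(active3)),
    active_dist_y1 = tabulate(k1[pool], 4) / sum(pool),
    tau = list(cost = mean(tau_total), cost_se = se(tau_total),
               qaly = mean(rowSums(tau_util)), qaly_se = se(rowSums(tau_util))),
    dtx = list(cost = mean(dtx_total), cost_se = se(dtx_total),
               qaly = mean(rowSums(dtx_util)), qaly_se = se(rowSums(dtx_util))),
    delta_savings = mean(tau_total - dtx_total),
    delta_savings_se = sqrt(se(tau_total)^2 + se(dtx_total)^2),
    delta_qaly = mean(rowSums(dtx_util)) - mean(rowSums(tau_util)),
    delta_qaly_se = sqrt(se(rowSums(dtx_util))^2 + se(rowSums(tau_util))^2),
    pppm = stats::setNames(pppm, c("y1", "y2", "y3")),
    pppm_se = stats::setNames(pppm_se, c("y1", "y2", "y3"))
  )
}
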