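#' Classify a biomarker value into an outcome category
#'
#' Maps an HbA1c (T2DM) or SBP (HTN) value to outcome category 1-4 using the
#' disease's cut-points. Intervals are left-closed on their printed lower
#' bound; for T2DM the category-3 interval is additionally closed above
#' (HbA1c 9.0\% is category 3), while for HTN an SBP of 140 mm Hg is already
#' category 4.
#'
#' @param disease A `dtx_disease` object (see [disease_model()]).
#' @param value Biomarker value(s), finite and positive.
#' @return Integer category/categories in 1-4.
#' @examples
#' classify_biomarker(disease_model("T2DM"), c(6.4, 6.5, 9.0, 9.01))
#' classify_biomarker(disease_model("HTN"), c(119, 120, 139.9, 140))
#' @export
classify_biomarker <- function(disease, value) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("biomarker values must be finite and positive", call. = FALSE)
  }
  b <- disease$category_bounds
  cat3_top <- if (disease$upper_inclusive) {
    value <= b[3]
  } else {
    value < b[3]
  }
  ifelse(value < b[1], 1L, ifelse(value < b[2], 2L, ifelse(cat3_top, 3L, 4L)))
}

#' TAU persistence transition matrix
#'
#' Row-stochastic 4x4 matrix for the treatment-as-usual arm: each category
#' keeps `persistence` mass on the diagonal and spreads the remainder over
#' the adjacent categories. Under the default symmetric-adjacent rule the
#' spill splits equally between the two neighbours, reflecting inward at the
#' boundary categories (all spill from category 1 goes to 2, all spill from
#' category 4 goes to 3).
#'
#' @param persistence Fraction in \[0,1\] remaining in category each year
#'   (base case 0.80).
#' @param spill_rule `"symmetric_adjacent"` (default), `"all_worsen"`, or
#'   `"all_improve"`.
#' @return A 4x4 row-stochastic matrix.
#' @export
tau_transition_matrix <- function(persistence,
                                  spill_rule = c("symmetric_adjacent",
                                                 "all_worsen", "all_improve")) {
  spill_rule <- match.arg(spill_rule)
  if (persistence < 0 || persistence > 1) {
    stop("persistence must be in [0,1]", call. = FALSE)
  }
  s <- 1 - persistence
  P <- diag(rep(persistence, 4))
  spill_to <- function(k) {
    switch(spill_rule,
      symmetric_adjacent = {
        if (k == 1) c(2) else if (k == 4) c(3) else c(k - 1, k + 1)
      },
      all_worsen = if (k == 4) c(3) else c(k + 1),
      all_improve = if (k == 1) c(2) else c(k - 1)
    )
  }
  for (k in 1:4) {
    to <- spill_to(k)
    P[k, to] <- P[k, to] + s / length(to)
  }
  P
}

#' One TAU-arm transition step
#'
#' @param current A length-4 category distribution (sums to 1).
#' @param persistence Diagonal persistence fraction.
#' @param spill_rule See [tau_transition_matrix()].
#' @return The next-year category distribution.
#' @export
tau_transition <- function(current, persistence,
                           spill_rule = "symmetric_adjacent") {
  stopifnot(length(current) == 4, abs(sum(current) - 1) < 1e-9)
  as.numeric(current %*% tau_transition_matrix(persistence, spill_rule))
}

#' One DTx-arm transition step
#'
#' Applies the year's row-stochastic transition matrix to the current active
#' distribution.
#'
#' @param current A length-4 category distribution.
#' @param year Model year 1, 2, or 3.
#' @param tables Transition tables as produced by
#'   [synthesize_transition_tables()] or [transition_tables_from_csv()].
#' @return The end-of-year category distribution of active participants.
#' @export
dtx_transition <- function(current, year, tables) {
  if (year < 1 || year > length(tables$dtx)) {
    stop(sprintf("no DTx transition table for year %s", year), call. = FALSE)
  }
  M <- tables$dtx[[year]]
  if (any(abs(rowSums(M) - 1) > 1e-9)) {
    stop(sprintf("DTx year-%d table is not row-stochastic", year), call. = FALSE)
  }
  as.numeric(current %*% M)
}

#' Attrition arithmetic
#'
#' Computes the retained fraction of original enrollees active in the DTx
#' program at the end of each year, and the mass of each withdrawal stratum,
#' from the attrition schedule. With the base-case schedule (20\% at month 3
#' of year 1, a further 20\% at the end of year 1, 10\% during each of years
#' 2 and 3) retention is 0.64, 0.576 and 0.5184, i.e. 36\% of enrollees
#' withdraw by the end of year 1.
#'
#' @param schedule The `attrition` component of a `dtx_params` object.
#' @return List with `retained` (end-of-year fractions, length 3) and
#'   `strata` masses: `w_early` (month-3 year-1), `w_y1_late` (end of year
#'   1), `w_y2`, `w_y3` (mid-year withdrawals in years 2 and 3).
#' @export
attrition_masses <- function(schedule) {
  a <- schedule
  r1 <- (1 - a$y1_early) * (1 - a$y1_late)
  r2 <- r1 * (1 - a$y2)
  r3 <- r2 * (1 - a$y3)
  list(
    retained = c(r1, r2, r3),
    strata = list(
      w_early = a$y1_early,
      w_y1_late = (1 - a$y1_early) * a$y1_late,
      w_y2 = r1 * a$y2,
      w_y3 = r2 * a$y3
    )
  )
}

#' Simulate a cohort arm through the 3-year decision tree
#'
#' Deterministically evolves one arm: the TAU arm applies the persistence
#' transition each year with no program attrition; the DTx arm applies the
#' year-specific transition tables to active participants and peels off
#' withdrawal strata per the attrition schedule. Year-1 withdrawers return
#' to their enrollment category; year-2/3 withdrawers return to the average
#' TAU-only outcomes of each subsequent year.
#'
#' @param params A validated `dtx_params` object.
#' @param arm `"DTX_TAU"` or `"TAU"`.
#' @param tables Optional transition tables; when `NULL` they are taken from
#'   `params$transition_tables` or synthesized from the effectiveness
#'   constraints.
#' @return A list of class `dtx_trajectory` with fields `arm`, `enrollment`,
#'   `active_dist` (list of end-of-year distributions for the active
#'   stratum), `tau_dist` (TAU-arm distributions, used by return rules),
#'   `retained` (end-of-year retained fractions) and `strata` masses.
#' @export
simulate_cohort <- function(params, arm = c("DTX_TAU", "TAU"), tables = NULL) {
  arm <- match.arg(arm)
  e <- params$enrollment
  P <- tau_transition_matrix(params$tau_persistence)
  tau_dist <- vector("list", 3)
  d <- e
  for (y in 1:3) {
    d <- as.numeric(d %*% P)
    tau_dist[[y]] <- d
  }
  if (arm == "TAU") {
    out <- list(
      arm = arm, enrollment = e, active_dist = tau_dist, tau_dist = tau_dist,
      retained = c(1, 1, 1),
      strata = list(w_early = 0, w_y1_late = 0, w_y2 = 0, w_y3 = 0)
    )
    class(out) <- "dtx_trajectory"
    return(out)
  }
  if (is.null(tables)) {
    tables <- params$transition_tables
    if (is.null(tables)) tables <- synthesize_transition_tables(params)
  }
  att <- attrition_masses(params$attrition)
  active_dist <- vector("list", 3)
  d <- e
  for (y in 1:3) {
    d <- dtx_transition(d, y, tables)
    active_dist[[y]] <- d
  }
  out <- list(
    arm = arm, enrollment = e, active_dist = active_dist, tau_dist = tau_dist,
    retained = att$retained, strata = att$strata, tables = tables
  )
  class(out) <- "dtx_trajectory"
  out
}

#' Per-year occupancy segments of a trajectory
#'
#' Decomposes a trajectory year into exposure segments (mass, fraction of
#' the year, category distribution, costing style). This is the single place
#' where the within-year timing rules live: year-1 actives accrue
#' average-TAU-state outcomes for the benefit-delay months and their
#' end-of-year DTx-state outcomes thereafter (handled downstream via
#' the `delayed` flag), so the year-1 saving versus TAU is scaled by
#' `(12 - delay)/12` exactly; month-3 year-1 withdrawers accrue enrollment-state
#' TAU-style outcomes for the whole year; year-2/3 withdrawers split the
#' withdrawal year half-and-half between their active DTx state and the
#' year's average TAU state.
#'
#' @param trajectory A `dtx_trajectory`.
#' @param year Model year 1-3.
#' @return A list of segments, each with `mass`, `frac` (of the year),
#'   `dist`, `style` (`"dtx"` or `"tau"`) and `delayed` (logical: year-1
#'   benefit delay applies).
#' @keywords internal
trajectory_segments <- function(trajectory, year) {
  tr <- trajectory
  if (tr$arm == "TAU") {
    return(list(list(mass = 1, frac = 1, dist = tr$tau_dist[[year]],
                     style = "tau", delayed = FALSE)))
  }
  s <- tr$strata
  segs <- list()
  push <- function(mass, frac, dist, style, delayed = FALSE) {
    if (mass > 0 && frac > 0) {
      segs[[length(segs) + 1]] <<- list(mass = mass, frac = frac, dist = dist,
                                        style = style, delayed = delayed)
    }
  }
  if (year == 1) {
    # post-month-3 pool (actives + end-of-year withdrawers), delay-gated
    push(1 - s$w_early, 1, tr$active_dist[[1]], "dtx", delayed = TRUE)
    push(s$w_early, 1, tr$enrollment, "tau")
  } else if (year == 2) {
    push(tr$retained[2], 1, tr$active_dist[[2]], "dtx")
    push(s$w_y2, 0.5, tr$active_dist[[2]], "dtx")
    push(s$w_y2, 0.5, tr$tau_dist[[2]], "tau")
    push(s$w_early + s$w_y1_late, 1, tr$enrollment, "tau")
  } else {
    push(tr$retained[3], 1, tr$active_dist[[3]], "dtx")
    push(s$w_y3, 0.5, tr$active_dist[[3]], "dtx")
    push(s$w_y3, 0.5, tr$tau_dist[[3]], "tau")
    push(s$w_y2, 1, tr$tau_dist[[3]], "tau")
    push(s$w_early + s$w_y1_late, 1, tr$enrollment, "tau")
  }
  segs
}

#' Total cohort mass accounted for in a model year
#'
#' Conservation diagnostic: sums mass x year-fraction over all segments of
#' the year; equals 1 for a valid trajectory.
#'
#' @param trajectory A `dtx_trajectory`.
#' @param year Model year 1-3.
#' @return Scalar total mass.
#' @export
cohort_mass <- function(trajectory, year) {
  sum(vapply(trajectory_segments(trajectory, year),
             function(s) s$mass * s$frac, numeric(1)))
}
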