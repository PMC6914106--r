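#' Disease model definitions
#'
#' A disease model is identified by `"T2DM"` or `"HTN"` and carries the
#' biomarker label, the three ordered cut-points defining outcome categories
#' 1-4, and the representative (costing) biomarker values used when a single
#' number per category is needed. Category 1 is best (optimized biomarker),
#' category 4 worst.
#'
#' Boundary convention: categories are left-closed on the printed lower bound
#' of each interval. For T2DM the category-3 interval is closed above
#' (an HbA1c of exactly 9.0\% is category 3); for HTN a SBP of exactly
#' 140 mm Hg is category 4.
#'
#' @param id `"T2DM"` or `"HTN"`.
#' @return A list of class `dtx_disease` with fields `id`, `biomarker`,
#'   `category_bounds` (3 increasing cut-points), `upper_inclusive` (is the
#'   category-3 upper bound included in category 3), `rep_floor`, `rep_cap`
#'   (finite representative limits for the open outer bins) and
#'   `rep_values` (representative biomarker value per category, bin
#'   midpoints with the outer bins closed at `rep_floor`/`rep_cap`).
#' @export
disease_model <- function(id = c("T2DM", "HTN")) {
  id <- match.arg(id)
  d <- switch(id,
    T2DM = list(
      id = "T2DM", biomarker = "HbA1c (%)",
      category_bounds = c(6.5, 7.5, 9.0),
      upper_inclusive = TRUE,
      rep_floor = 5.5, rep_cap = 12.0
    ),
    HTN = list(
      id = "HTN", biomarker = "SBP (mm Hg)",
      category_bounds = c(120, 130, 140),
      upper_inclusive = FALSE,
      # Representative SBP in the >140 bin caps at 162 mm Hg (midpoint
      # 151), the value at which the two printed year-1 effectiveness
      # constraints (87% responders, -11 mm Hg mean change) are jointly
      # satisfiable under a move-one-category response structure.
      rep_floor = 110, rep_cap = 162
    )
  )
  b <- d$category_bounds
  d$rep_values <- c(
    (d$rep_floor + b[1]) / 2,
    (b[1] + b[2]) / 2,
    (b[2] + b[3]) / 2,
    (b[3] + d$rep_cap) / 2
  )
  class(d) <- "dtx_disease"
  d
}

#' Base-case model parameters
#'
#' Returns the full validated base-case parameter set for one disease model:
#' enrollment distribution, comorbidity prevalences, DTx effectiveness
#' constraints, attrition schedule, medication cost gradients, CVD inputs,
#' health-state utilities, clinical-inertia delays and discounting.
#'
#' Three quantities are not published as point inputs and ship as
#' *calibrated* values (clearly marked in the registry): the year-2/3
#' incremental improvement fractions of active participants, the baseline
#' annual CVD event rate that the T2DM hazard ratios multiply, and a scale
#' factor on the Framingham-derived CVD rates in the HTN model. They are set
#' by [calibrate_base_case()] so that the base-case per-participant-per-month
#' (PPPM) savings reproduce the published base case; see the methods
#' vignette.
#'
#' @param disease `"T2DM"` or `"HTN"`.
#' @return A list of class `dtx_params`; see the package vignette for the
#'   field-by-field description.
#' @examples
#' p <- default_parameters("T2DM")
#' p$med_costs$T2DM$base        # 2466 USD/year
#' p$enrollment                 # no enrollees start in category 1
#' @export
default_parameters <- function(disease = c("T2DM", "HTN")) {
  disease <- match.arg(disease)
  common <- list(
    mean_age = 50,
    female_fraction = 0.5,
    tau_persistence = 0.80,
    attrition = list(
      y1_early = 0.20, y1_late = 0.20, y2 = 0.10, y3 = 0.10,
      y1_return = "to_enrollment", y23_return = "to_tau_average",
      y1_early_month = 3, y23_withdrawal_month = 6
    ),
    cat2_unmedicated_fraction = 0.25,
    delays = list(medication_months = 6, cvd_months = 3),
    discount_rate = 0.03,
    horizon_years = 3,
    transition_tables = NULL
  )
  if (disease == "T2DM") {
    p <- c(list(
      disease = disease_model("T2DM"),
      enrollment = c(0, 0.47, 0.34, 0.19),
      primary_med = "T2DM",
      comorbidity_prevalence = c(HC = 0.60, HTN = 0.60),
      med_costs = list(
        T2DM = list(base = 2466, slopes = c(0, 0.33, 1.2, 2.2)),
        HC   = list(base = 775,  slopes = c(0.5, 0.8, 1.5, 2.0)),
        HTN  = list(base = 1557, slopes = c(0, 0.15, 0.9, 1.8))
      ),
      effectiveness = list(
        responder_fraction_y1 = 0.62,
        mean_change_y1 = -0.8,
        two_category_fraction = 0,
        # calibrated: fraction of active participants improving one
        # category in years 2 and 3 ("small improvements")
        y2_improvement = .dtx_calibrated$T2DM$y2_improvement,
        y3_improvement = .dtx_calibrated$T2DM$y3_improvement,
        category4_damping = 0.5
      ),
      cvd = list(
        event_cost = 116423,
        model = "hazard_ratio",
        hazard_ratios = c(1, 1, 1.25, 1.98),
        # calibrated placeholder: category-1/2 reference annual CVD event
        # rate (events/person-year); not published in the main text
        baseline_annual_rate = .dtx_calibrated$T2DM$baseline_annual_rate,
        risk_scale = 1
      ),
      utilities = list(
        anchor = 0.82, cat1_inc = 0.02, cat2_meds_inc = -0.02,
        cat3_inc = -0.035, cat4_inc = -0.025, cvd_event_inc = -0.1,
        increment_mode = "cumulative"
      )
    ), common)
  } else {
    p <- c(list(
      disease = disease_model("HTN"),
      enrollment = c(0, 0.37, 0.19, 0.44),
      primary_med = "HTN",
      comorbidity_prevalence = c(T2DM = 0.33),
      med_costs = list(
        HTN  = list(base = 1557, slopes = c(0, 0.15, 0.9, 1.8)),
        T2DM = list(base = 2466, slopes = c(0, 0.33, 1.2, 2.2))
      ),
      effectiveness = list(
        responder_fraction_y1 = 0.87,
        mean_change_y1 = -11,
        two_category_fraction = 0,
        y2_improvement = .dtx_calibrated$HTN$y2_improvement,
        y3_improvement = .dtx_calibrated$HTN$y3_improvement,
        category4_damping = 0.5
      ),
      cvd = list(
        event_cost = 116423,
        model = "framingham",
        hazard_ratios = NULL,
        baseline_annual_rate = NULL,
        # calibrated multiplier on Framingham-derived event rates; absorbs
        # the uncertainty of the representative risk profile
        risk_scale = .dtx_calibrated$HTN$risk_scale,
        framingham = list(
          total_cholesterol = 200, hdl_cholesterol = 50,
          smoker_fraction = 0.14, diabetic_fraction = 0.33,
          treated = c(FALSE, TRUE, TRUE, TRUE)
        )
      ),
      utilities = list(
        anchor = 0.83, cat1_inc = 0.025, cat2_meds_inc = -0.01,
        cat3_inc = -0.03, cat4_inc = 0, cvd_event_inc = -0.1,
        increment_mode = "cumulative"
      )
    ), common)
  }
  class(p) <- "dtx_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks every structural invariant of a `dtx_params` object: category
#' cut-points strictly increasing; enrollment a distribution with no mass in
#' category 1; all fractions in \[0,1\]; medication gradients non-negative
#' and non-decreasing across categories; costs non-negative; realized
#' utilities in \[0,1\]; discount rate within its sensitivity range
#' \[0, 0.05\]; and, when transition tables are attached, row-stochastic rows
#' (within 1e-9) with the TAU diagonal at or above the configured
#' persistence.
#'
#' @param params A `dtx_params` object.
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameters: [%s] %s", field, msg), call. = FALSE)
  }
  frac01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)

  b <- params$disease$category_bounds
  if (length(b) != 3 || any(diff(b) <= 0)) {
    fail("disease$category_bounds", "must be 3 strictly increasing cut-points")
  }
  e <- params$enrollment
  if (length(e) != 4 || !frac01(e)) fail("enrollment", "must be 4 fractions in [0,1]")
  if (abs(sum(e) - 1) > 1e-9) {
    fail("enrollment", sprintf("must sum to 1 (got %.6f)", sum(e)))
  }
  if (e[1] != 0) fail("enrollment", "category-1 share must be 0 at enrollment")

  at <- params$attrition
  if (!frac01(c(at$y1_early, at$y1_late, at$y2, at$y3))) {
    fail("attrition", "all attrition fractions must be in [0,1]")
  }
  if (!frac01(params$tau_persistence)) fail("tau_persistence", "must be in [0,1]")
  if (!frac01(params$cat2_unmedicated_fraction)) {
    fail("cat2_unmedicated_fraction", "must be in [0,1]")
  }
  if (!frac01(params$comorbidity_prevalence)) {
    fail("comorbidity_prevalence", "prevalences must be in [0,1]")
  }

  for (nm in names(params$med_costs)) {
    g <- params$med_costs[[nm]]
    if (g$base < 0) fail(paste0("med_costs$", nm), "base cost must be >= 0")
    if (length(g$slopes) != 4 || any(g$slopes < 0) || any(diff(g$slopes) < 0)) {
      fail(paste0("med_costs$", nm),
           "slopes must be 4 non-negative, non-decreasing multipliers")
    }
  }

  cv <- params$cvd
  if (cv$event_cost < 0) fail("cvd$event_cost", "must be >= 0")
  if (identical(cv$model, "hazard_ratio")) {
    if (length(cv$hazard_ratios) != 4 || any(cv$hazard_ratios <= 0)) {
      fail("cvd$hazard_ratios", "must be 4 positive multipliers")
    }
    if (is.null(cv$baseline_annual_rate) || cv$baseline_annual_rate < 0) {
      fail("cvd$baseline_annual_rate", "must be a non-negative rate")
    }
  }

  eff <- params$effectiveness
  if (!frac01(eff$responder_fraction_y1)) {
    fail("effectiveness$responder_fraction_y1", "must be in [0,1]")
  }
  if (!frac01(c(eff$y2_improvement, eff$y3_improvement))) {
    fail("effectiveness$y2_improvement", "improvement fractions must be in [0,1]")
  }
  if (eff$category4_damping <= 0 || eff$category4_damping > 1) {
    fail("effectiveness$category4_damping", "must be in (0,1]")
  }

  u <- realized_utilities(params$utilities)
  if (!frac01(unlist(u))) fail("utilities", "realized utilities must lie in [0,1]")

  dl <- params$delays
  if (dl$medication_months < 0 || dl$medication_months > 12 ||
      dl$cvd_months < 0 || dl$cvd_months > 12) {
    fail("delays", "delay months must be in [0,12]")
  }
  if (params$discount_rate < 0 || params$discount_rate > 0.05) {
    fail("discount_rate", "must be in [0, 0.05]")
  }
  if (params$horizon_years != 3) fail("horizon_years", "model horizon is 3 years")

  tt <- params$transition_tables
  if (!is.null(tt)) {
    for (y in seq_along(tt$dtx)) {
      M <- tt$dtx[[y]]
      bad <- which(abs(rowSums(M) - 1) > 1e-9)
      if (length(bad) > 0) {
        fail("transition_tables",
             sprintf("DTx year-%d rows not stochastic: row(s) %s",
                     y, paste(bad, collapse = ", ")))
      }
      if (any(M < -1e-12)) {
        fail("transition_tables", sprintf("DTx year-%d has negative entries", y))
      }
    }
    P <- tau_transition_matrix(params$tau_persistence)
    if (any(diag(P) < params$tau_persistence - 1e-9)) {
      fail("transition_tables", "TAU diagonal below configured persistence")
    }
  }
  invisible(params)
}

#' Realized health-state utilities
#'
#' Expands a utility specification into the per-category utilities actually
#' used by the model. Under `increment_mode = "cumulative"` (the default) the
#' increments chain from the anchor (category 2 without medications):
#' category 1 = anchor + cat1 increment; category 2 on medications = anchor +
#' cat2 increment; category 3 = category-2-on-meds + cat3 increment;
#' category 4 = category 3 + cat4 increment. Under `"absolute"` every
#' increment is taken directly from the anchor. Cumulative is the default
#' because it yields utilities that are monotone in disease severity for
#' both published parameter sets.
#'
#' @param utilities The `utilities` component of a `dtx_params` object.
#' @return List with `cat1`, `cat2_no_meds`, `cat2_meds`, `cat3`, `cat4`.
#' @export
realized_utilities <- function(utilities) {
  u <- utilities
  a <- u$anchor
  c2m <- a + u$cat2_meds_inc
  if (identical(u$increment_mode, "cumulative")) {
    c3 <- c2m + u$cat3_inc
    c4 <- c3 + u$cat4_inc
  } else if (identical(u$increment_mode, "absolute")) {
    c3 <- a + u$cat3_inc
    c4 <- a + u$cat4_inc
  } else {
    stop("increment_mode must be 'cumulative' or 'absolute'", call. = FALSE)
  }
  list(cat1 = a + u$cat1_inc, cat2_no_meds = a, cat2_meds = c2m,
       cat3 = c3, cat4 = c4)
}

# ---------------------------------------------------------------------------
# Sensitivity-analysis registry

#' Sensitivity-analysis parameter registry
#'
#' Enumerates every model parameter with a declared one-way
#' sensitivity-analysis range for the given disease model, with its base
#' value and low/high bounds. Most parameters vary by +/-20\%; DTx
#' effectiveness is asymmetric (+20\%/-40\% on mean improvement,
#' +10\%/-33\% on the responder fraction), comorbidity prevalence in T2DM is
#' +10\%/-30\%, the category-2 unmedicated share spans 0\%-50\%, delays vary
#' by +/-3 (medication) and +/-1 (CVD) months, and the discount rate spans
#' 0\%-5\%. Gradient- and hazard-ratio-valued parameters scale every element
#' of the tuple by the same +/-10\% factor.
#'
#' @param params A `dtx_params` object.
#' @return A data.frame with columns `name`, `units`, `kind`
#'   (`scalar`/`scale`/`effectiveness`), `base`, `sa_low`, `sa_high`,
#'   `printed_range` (the published range annotation), plus an attribute
#'   carrying the setter used by [apply_sa_bound()].
#' @export
sa_registry <- function(params) {
  rows <- list()
  add <- function(name, units, kind, base, low, high, printed, setter) {
    rows[[length(rows) + 1]] <<- list(
      name = name, units = units, kind = kind, base = base,
      sa_low = low, sa_high = high, printed_range = printed, setter = setter
    )
  }
  set_in <- function(...) {
    path <- c(...)
    function(p, v) {
      p[[path]] <- v
      p
    }
  }
  scale_in <- function(...) {
    path <- c(...)
    function(p, v) {
      p[[path]] <- p[[path]] * v
      p
    }
  }

  add("mean_age", "years", "scalar", params$mean_age,
      params$mean_age - 5, params$mean_age + 5, "+/-5", set_in("mean_age"))
  add("responder_fraction", "scale factor", "effectiveness", 1, 0.67, 1.10,
      "+10/-33%", effectiveness_rescaler())
  add("mean_improvement", "scale factor", "effectiveness", 1, 0.60, 1.20,
      "+20/-40%", effectiveness_rescaler())
  add("cat2_unmedicated_fraction", "fraction", "scalar",
      params$cat2_unmedicated_fraction, 0, 0.50, "0/50%",
      set_in("cat2_unmedicated_fraction"))

  for (nm in names(params$comorbidity_prevalence)) {
    base <- unname(params$comorbidity_prevalence[nm])
    if (params$disease$id == "T2DM") {
      lo <- base * 0.70; hi <- base * 1.10; printed <- "+10/-30%"
    } else {
      lo <- base * 0.80; hi <- base * 1.20; printed <- "+/-20%"
    }
    setter <- local({
      nm0 <- nm
      function(p, v) {
        p$comorbidity_prevalence[nm0] <- v
        p
      }
    })
    add(paste0("comorbid_", nm, "_prevalence"), "fraction", "scalar",
        base, lo, hi, printed, setter)
  }

  for (nm in names(params$med_costs)) {
    base <- params$med_costs[[nm]]$base
    add(paste0(nm, "_med_annual_cost"), "USD/year", "scalar", base,
        base * 0.8, base * 1.2, "+/-20%", set_in("med_costs", nm, "base"))
    add(paste0(nm, "_med_gradient"), "scale factor", "scale", 1, 0.9, 1.1,
        "+/-10%", scale_in("med_costs", nm, "slopes"))
  }

  add("cvd_event_cost", "USD", "scalar", params$cvd$event_cost,
      params$cvd$event_cost * 0.8, params$cvd$event_cost * 1.2, "+/-20%",
      set_in("cvd", "event_cost"))
  if (identical(params$cvd$model, "hazard_ratio")) {
    add("cvd_hazard_ratios", "scale factor", "scale", 1, 0.9, 1.1, "+/-10%",
        scale_in("cvd", "hazard_ratios"))
  }

  for (nm in c("cat1_inc", "cat2_meds_inc", "cat3_inc", "cat4_inc",
               "cvd_event_inc")) {
    base <- params$utilities[[nm]]
    add(paste0("utility_", nm), "utility", "scalar", base,
        base - 0.2 * abs(base), base + 0.2 * abs(base), "+/-20%",
        set_in("utilities", nm))
  }

  add("medication_delay_months", "months", "scalar",
      params$delays$medication_months,
      params$delays$medication_months - 3, params$delays$medication_months + 3,
      "+/-3", set_in("delays", "medication_months"))
  add("cvd_delay_months", "months", "scalar", params$delays$cvd_months,
      params$delays$cvd_months - 1, params$delays$cvd_months + 1, "+/-1",
      set_in("delays", "cvd_months"))
  add("discount_rate", "fraction/year", "scalar", params$discount_rate,
      0, 0.05, "0/5%", set_in("discount_rate"))

  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r$name, units = r$units, kind = r$kind, base = r$base,
               sa_low = r$sa_low, sa_high = r$sa_high,
               printed_range = r$printed_range, stringsAsFactors = FALSE)
  }))
  attr(df, "setters") <- stats::setNames(
    lapply(rows, function(r) r$setter),
    vapply(rows, function(r) r$name, character(1))
  )
  df
}

# Joint rescale of DTx effectiveness: the responder fraction, mean change
# and year-2/3 improvement fractions move together, and the year-1 table is
# regenerated from the perturbed constraints.
effectiveness_rescaler <- function() {
  function(p, v) {
    eff <- p$effectiveness
    eff$responder_fraction_y1 <- min(1, eff$responder_fraction_y1 * v)
    eff$mean_change_y1 <- eff$mean_change_y1 * v
    eff$y2_improvement <- min(1, eff$y2_improvement * v)
    eff$y3_improvement <- min(1, eff$y3_improvement * v)
    p$effectiveness <- eff
    p$transition_tables <- NULL # force re-synthesis under the new constraints
    p
  }
}

#' Set one parameter to a sensitivity-analysis bound
#'
#' Returns a copy of `params` with the named parameter moved to its declared
#' low or high bound, everything else unchanged. Asymmetric published ranges
#' are honored. Effectiveness bounds rescale the responder fraction, mean
#' biomarker change and year-2/3 improvements jointly and trigger
#' re-synthesis of the transition tables.
#'
#' @param params A `dtx_params` object.
#' @param parameter_name A name from [sa_registry()].
#' @param direction `"low"` or `"high"`.
#' @return A modified `dtx_params` object (the input is never mutated).
#' @export
apply_sa_bound <- function(params, parameter_name, direction = c("low", "high")) {
  direction <- match.arg(direction)
  reg <- sa_registry(params)
  i <- match(parameter_name, reg$name)
  if (is.na(i)) {
    stop(sprintf("unknown SA parameter '%s'; see sa_registry()", parameter_name),
         call. = FALSE)
  }
  v <- if (direction == "low") reg$sa_low[i] else reg$sa_high[i]
  setter <- attr(reg, "setters")[[parameter_name]]
  setter(params, v)
}

#' Export the parameter registry
#'
#' Writes (or returns) the full sensitivity registry as a plain data.frame
#' suitable for CSV export: name, base value, SA bounds and units.
#'
#' @param params A `dtx_params` object.
#' @param file Optional path; when given, the registry is written as CSV.
#' @return The registry data.frame, invisibly when `file` is given.
#' @export
parameter_registry <- function(params, file = NULL) {
  reg <- sa_registry(params)
  attr(reg, "setters") <- NULL
  if (!is.null(file)) {
    utils::write.csv(reg, file, row.names = FALSE)
    return(invisible(reg))
  }
  reg
}

# ---------------------------------------------------------------------------
# Serialization

#' Serialize parameters to YAML
#'
#' @param params A `dtx_params` object.
#' @param file Optional path to write to; when `NULL` the YAML text is
#'   returned.
#' @return YAML text (invisibly when written to `file`).
#' @export
write_parameters <- function(params, file = NULL) {
  x <- unclass(params)
  x$disease <- unclass(x$disease)
  x$disease$rep_values <- NULL # derived; recomputed on load
  # named atomic vectors of length 1 lose their names in YAML; keep the
  # comorbidity map as an explicit mapping
  x$comorbidity_prevalence <- as.list(x$comorbidity_prevalence)
  if (!is.null(x$transition_tables)) {
    x$transition_tables <- lapply(x$transition_tables, function(arm) {
      lapply(arm, function(M) as.list(as.data.frame(t(M))))
    })
  }
  txt <- yaml::as.yaml(x, precision = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Load parameters from YAML
#'
#' Reads a parameter configuration (as written by [write_parameters()], or
#' hand-edited). Keys that are absent fall back to the base case for the
#' configured disease with a notice; present keys override. The result is
#' validated before being returned.
#'
#' @param file Path to a YAML file, or a YAML string.
#' @return A validated `dtx_params` object.
#' @export
load_parameters <- function(file) {
  is_path <- length(file) == 1 && !grepl("\n", file)
  x <- if (is_path && file.exists(file)) yaml::read_yaml(file) else yaml::yaml.load(file)
  if (is.null(x$disease) || is.null(x$disease$id)) {
    stop("config must contain disease: id: T2DM or HTN", call. = FALSE)
  }
  base <- default_parameters(x$disease$id)
  merged <- modify_defaults(unclass(base), x)
  merged$disease <- disease_model(x$disease$id)
  for (f in c("category_bounds", "rep_floor", "rep_cap")) {
    if (!is.null(x$disease[[f]])) merged$disease[[f]] <- x$disease[[f]]
  }
  b <- merged$disease$category_bounds
  merged$disease$rep_values <- c(
    (merged$disease$rep_floor + b[1]) / 2, (b[1] + b[2]) / 2,
    (b[2] + b[3]) / 2, (b[3] + merged$disease$rep_cap) / 2
  )
  if (!is.null(x$transition_tables)) {
    merged$transition_tables <- lapply(x$transition_tables, function(arm) {
      lapply(arm, function(rows) {
        M <- t(vapply(rows, as.numeric, numeric(4)))
        dimnames(M) <- NULL
        M
      })
    })
  }
  for (nm in setdiff(names(base), names(x))) {
    message(sprintf("load_parameters: '%s' not in config, using base case", nm))
  }
  if (!is.null(merged$enrollment)) merged$enrollment <- as.numeric(merged$enrollment)
  if (!is.null(merged$comorbidity_prevalence)) {
    merged$comorbidity_prevalence <- unlist(merged$comorbidity_prevalence)
  }
  class(merged) <- "dtx_params"
  validate_parameters(merged)
  merged
}

# Recursive default merge: values present in `override` win; nested lists
# merge by name.
modify_defaults <- function(base, override) {
  if (!is.list(base) || !is.list(override) || is.null(names(override))) {
    return(override)
  }
  for (nm in names(override)) {
    base[[nm]] <- if (nm %in% names(base)) {
      modify_defaults(base[[nm]], override[[nm]])
    } else {
      override[[nm]]
    }
  }
  base
}
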