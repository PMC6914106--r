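#' Evaluate one model outcome
#'
#' @param params A `dtx_params` object.
#' @param outcome One of `"pppm_y1"`, `"pppm_y2"`, `"pppm_y3"`,
#'   `"pppm_avg"`, `"breakeven_50k"`, `"breakeven_100k"`, `"delta_qaly"`.
#' @return Scalar outcome value.
#' @export
model_outcome <- function(params,
                          outcome = c("pppm_y1", "pppm_y2", "pppm_y3",
                                      "pppm_avg", "breakeven_50k",
                                      "breakeven_100k", "delta_qaly")) {
  outcome <- match.arg(outcome)
  run <- run_model(params)
  switch(outcome,
    pppm_y1 = unname(run$pppm["y1"]),
    pppm_y2 = unname(run$pppm["y2"]),
    pppm_y3 = unname(run$pppm["y3"]),
    pppm_avg = unname(run$pppm["avg"]),
    breakeven_50k = run$cea$breakeven(50000),
    breakeven_100k = run$cea$breakeven(100000),
    delta_qaly = run$cea$delta_qaly
  )
}

#' One-way deterministic sensitivity analysis
#'
#' For each parameter with a declared sensitivity range, re-runs the full
#' model at the low and high bound with everything else at base, and sorts
#' the results by the outcome span (tornado order). The input parameter set
#' is never modified.
#'
#' @param params Base-case `dtx_params`.
#' @param outcome Outcome to tabulate; see [model_outcome()].
#' @param parameter_list Names from [sa_registry()]; defaults to all.
#' @return data.frame ordered by decreasing `span` with columns `rank`,
#'   `parameter`, `low_value`, `high_value`, `outcome_low`, `outcome_high`,
#'   `base_outcome`, `span`.
#' @export
one_way_sa <- function(params, outcome = "pppm_y1", parameter_list = NULL) {
  reg <- sa_registry(params)
  if (is.null(parameter_list)) parameter_list <- reg$name
  unknown <- setdiff(parameter_list, reg$name)
  if (length(unknown) > 0) {
    stop("unknown SA parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(parameter_list) == 0) {
    warning("empty parameter list: returning empty tornado table")
    return(data.frame(rank = integer(), parameter = character(),
                      low_value = numeric(), high_value = numeric(),
                      outcome_low = numeric(), outcome_high = numeric(),
                      base_outcome = numeric(), span = numeric()))
  }
  base_outcome <- model_outcome(params, outcome)
  rows <- lapply(parameter_list, function(nm) {
    i <- match(nm, reg$name)
    lo <- model_outcome(apply_sa_bound(params, nm, "low"), outcome)
    hi <- model_outcome(apply_sa_bound(params, nm, "high"), outcome)
    data.frame(parameter = nm, low_value = reg$sa_low[i],
               high_value = reg$sa_high[i], outcome_low = lo,
               outcome_high = hi, base_outcome = base_outcome,
               span = abs(hi - lo))
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$span), ]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Named scenario and override runs
#'
#' Runs the full model under a named scenario or an arbitrary set of
#' parameter overrides. Bundled scenarios restrict the enrollment severity
#' mix (renormalizing the enrollment distribution):
#' \describe{
#'   \item{`severity_34_only` / `high_cost_high_effectiveness`}{enroll only
#'     categories 3-4 (0\% category 2).}
#'   \item{`severity_4_only`}{enroll only category 4.}
#' }
#'
#' @param params Base `dtx_params`.
#' @param scenario Optional scenario name.
#' @param overrides Optional named list applied to the parameter object
#'   (top-level or nested via [utils::modifyList()] semantics).
#' @return A `dtx_run` (see [run_model()]).
#' @export
scenario_run <- function(params, scenario = NULL, overrides = NULL) {
  p <- params
  if (!is.null(scenario)) {
    keep <- switch(scenario,
      severity_34_only = ,
      high_cost_high_effectiveness = c(3, 4),
      severity_4_only = 4,
      stop(sprintf("unknown scenario '%s'", scenario), call. = FALSE)
    )
    e <- numeric(4)
    e[keep] <- p$enrollment[keep]
    if (sum(e) <= 0) {
      stop("scenario removes all enrollment mass", call. = FALSE)
    }
    p$enrollment <- e / sum(e)
    # the published mean biomarker change describes the base enrollment
    # mix; under a restricted mix only the responder fraction binds
    p$effectiveness$mean_change_y1 <- NA
    p$transition_tables <- NULL
  }
  if (!is.null(overrides)) {
    cl <- class(p)
    p <- modify_defaults(unclass(p), overrides)
    class(p) <- cl
  }
  validate_parameters(p)
  run_model(p)
}
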