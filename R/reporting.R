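#' Run the base case and write report files
#'
#' Runs the full model for one disease (base case or a YAML config) and
#' writes the standard report set to `out_dir`: the per-arm cost-breakdown
#' CSV (component by year, undiscounted and discounted, plus PPPM), the
#' PPPM savings table (years 1-3 and the 3-year average), the CEA JSON
#' (incremental savings, QALYs, break-even at the requested
#' willingness-to-pay values), the threshold-curve CSV and a run manifest.
#' Machine-readable files carry full precision; the printed summary rounds
#' to whole dollars.
#'
#' @param disease `"T2DM"` or `"HTN"` (ignored when `config_path` given).
#' @param config_path Optional YAML parameter config (see
#'   [load_parameters()]).
#' @param out_dir Output directory (created if needed).
#' @param wtp Willingness-to-pay grid for the threshold curve, USD/QALY.
#' @param quiet Suppress the console summary.
#' @return The `dtx_run`, invisibly.
#' @export
run_base_case <- function(disease = c("T2DM", "HTN"), config_path = NULL,
                          out_dir = ".", wtp = seq(0, 150000, by = 10000),
                          quiet = FALSE) {
  params <- if (!is.null(config_path)) {
    load_parameters(config_path)
  } else {
    default_parameters(match.arg(disease))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- run_model(params)
  id <- params$disease$id

  bd <- rbind(run$tau_costs, run$dtx_costs)
  bd$pppm <- bd$total / bd$person_months
  f_costs <- file.path(out_dir, paste0(id, "_cost_breakdown.csv"))
  utils::write.csv(bd, f_costs, row.names = FALSE)

  pppm_tab <- data.frame(
    year = c("1", "2", "3", "3-year average"),
    pppm_savings = unname(run$pppm)
  )
  f_pppm <- file.path(out_dir, paste0(id, "_pppm_savings.csv"))
  utils::write.csv(pppm_tab, f_pppm, row.names = FALSE)

  curve <- threshold_curve(run$cea, wtp)
  f_curve <- file.path(out_dir, paste0(id, "_threshold_curve.csv"))
  utils::write.csv(curve, f_curve, row.names = FALSE)

  cea <- list(
    disease = id,
    delta_savings = run$cea$delta_savings,
    delta_qaly = run$cea$delta_qaly,
    breakeven = stats::setNames(as.list(run$cea$breakeven(wtp)),
                                paste0("wtp_", wtp))
  )
  f_cea <- file.path(out_dir, paste0(id, "_cea.json"))
  jsonlite::write_json(cea, f_cea, auto_unbox = TRUE, digits = NA)

  f_config <- file.path(out_dir, paste0(id, "_config_used.yaml"))
  write_parameters(params, f_config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dtxcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    disease = id,
    config_md5 = unname(tools::md5sum(f_config)),
    outputs = basename(c(f_costs, f_pppm, f_curve, f_cea, f_config))
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(id, "_manifest.json")),
                       auto_unbox = TRUE)
  if (!quiet) print(run)
  invisible(run)
}

#' Run the one-way sensitivity analysis and write the tornado report
#'
#' @param disease `"T2DM"` or `"HTN"` (ignored when `config_path` given).
#' @param config_path Optional YAML parameter config.
#' @param outcome Outcome to rank by; see [model_outcome()].
#' @param out_dir Output directory.
#' @param parameter_list Optional subset of [sa_registry()] names.
#' @return The tornado data.frame, invisibly.
#' @export
run_sa <- function(disease = c("T2DM", "HTN"), config_path = NULL,
                   outcome = "pppm_y1", out_dir = ".", parameter_list = NULL) {
  params <- if (!is.null(config_path)) {
    load_parameters(config_path)
  } else {
    default_parameters(match.arg(disease))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tor <- one_way_sa(params, outcome, parameter_list)
  f <- file.path(out_dir, paste0(params$disease$id, "_tornado_", outcome, ".csv"))
  utils::write.csv(tor, f, row.names = FALSE)
  invisible(tor)
}
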