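## End-to-end screen orchestration: load -> preprocess -> fit -> rank ->
## export.  Deterministic: two runs with identical config and inputs produce
## identical result tables (fixed initialization, no random restarts).

#' Run a full thermal-unfolding screen analysis
#'
#' Reads a wide curves table (and optional plate layout), fits the requested
#' model(s) to every sample, assembles the stability table, and writes the
#' results CSV, a resolved-configuration JSON (provenance), a log of flagged
#' or skipped samples, the heatmap table CSV and a heatmap image.  Failures
#' of individual samples are logged and do not stop the run.
#'
#' @param input Path to the curves CSV (header `temperature,<id1>,...`).
#' @param layout Optional path to a layout CSV ([read_layout()] format).
#' @param model `"thermodynamic"`, `"kinetic"`, `"empirical"` or `"all"`.
#' @param out_dir Output directory (created if missing).
#' @param temperature_unit `"celsius"` or `"kelvin"` for the input file.
#' @param scan_rate Scan rate, K/min.
#' @param tref Reference temperature for extrapolated measures, kelvin.
#' @param reference Optional sample id used to add a ddG column.
#' @param heatmap_measure Measure for the heatmap outputs.
#' @param dCp Fixed heat-capacity change, J/mol/K.
#' @param smooth_window_k Optional median-filter window (K); `NULL` skips
#'   smoothing.
#' @param trim Optional `c(t_low, t_high)` in kelvin; `NULL` keeps the scan.
#' @param control A [fit_control()].
#' @return The stability table, invisibly; output files under `out_dir`.
#' @export
run_screen <- function(input, layout = NULL,
                       model = c("thermodynamic", "kinetic", "empirical", "all"),
                       out_dir = "meltcurve_results",
                       temperature_unit = c("celsius", "kelvin"),
                       scan_rate = 1.0, tref = .Tref_std, reference = NULL,
                       heatmap_measure = "dG_std", dCp = 0,
                       smooth_window_k = NULL, trim = NULL,
                       control = fit_control()) {
  model <- match.arg(model)
  temperature_unit <- match.arg(temperature_unit)
  if (!file.exists(input)) stop(sprintf("input file '%s' not found", input))
  if (!is.null(layout) && !file.exists(layout))
    stop(sprintf("layout file '%s' not found", layout))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    invisible(msg)
  }

  curves <- withCallingHandlers(
    read_curves(input, temperature_unit = temperature_unit,
                scan_rate = scan_rate),
    warning = function(w) {
      note("warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  note("loaded %d curves from %s", length(curves), input)
  lay <- if (!is.null(layout)) read_layout(layout) else NULL

  models <- if (model == "all") c("thermodynamic", "kinetic", "empirical") else model
  records <- list()
  for (id in names(curves)) {
    cv <- curves[[id]]
    if (!is.null(trim))
      cv <- tryCatch(trim_curve(cv, trim[1], trim[2]), error = function(e) {
        note("sample %s: %s", id, conditionMessage(e)); cv })
    if (!is.null(smooth_window_k)) cv <- smooth_median(cv, smooth_window_k)
    fits <- list()
    for (m in models) {
      f <- tryCatch(fit_unfolding(cv, model = m, dCp = dCp, control = control),
                    error = function(e) {
                      note("sample %s (%s): error: %s", id, m, conditionMessage(e))
                      NULL
                    })
      if (!is.null(f)) {
        fits[[m]] <- f
        if (length(f$flags))
          note("sample %s (%s): %s", id, m, paste(f$flags, collapse = ","))
      }
    }
    if (!length(fits)) next
    records[[id]] <- stability_measures(fits, tref = tref)
  }
  results <- do.call(rbind, records)
  rownames(results) <- NULL
  if (!is.null(lay)) {
    results <- merge(as.data.frame(lay)[, c("sample_id", "well",
                                            "condition_label",
                                            "replicate_group")],
                     results, by = "sample_id", all.y = TRUE, sort = FALSE)
  }
  if (!is.null(reference)) {
    ref_row <- results[results$sample_id == reference, , drop = FALSE]
    if (nrow(ref_row) == 1 && !is.na(ref_row$dG_std))
      results$ddG <- results$dG_std - ref_row$dG_std
    else note("reference sample '%s' missing or without dG; ddG skipped",
              reference)
  }

  write_results(results, file.path(out_dir, "results.csv"))
  cfg <- list(input = input, layout = layout, model = model,
              temperature_unit = temperature_unit, scan_rate = scan_rate,
              tref = tref, reference = reference,
              heatmap_measure = heatmap_measure, dCp = dCp,
              smooth_window_k = smooth_window_k, trim = trim,
              control = unclass(control))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(lay) && heatmap_measure %in% names(results) &&
      any(!is.na(results[[heatmap_measure]]))) {
    ht <- heatmap_table(results, lay, heatmap_measure)
    write.csv(as.data.frame(ht), file.path(out_dir, "heatmap_table.csv"),
              row.names = FALSE)
    try(plot_stability_heatmap(results, lay, heatmap_measure,
                               path = file.path(out_dir, "heatmap.png")),
        silent = TRUE)
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(results)
}
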