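## Stability measures, comparisons, correlation diagnostics and heatmaps.

#' Stability measures from fitted models
#'
#' Collapses one sample's fit(s) into a one-row stability record holding the
#' three single-number ranking measures:
#' * `dG_std` -- apparent standard Gibbs free energy of unfolding
#'   extrapolated to 298.15 K and 100 kPa (J/mol), from the thermodynamic fit;
#' * `pku_std` -- negative decadic log of the unfolding rate constant at
#'   298.15 K, from the kinetic fit;
#' * `Teucl` -- Euclidean combination of melting and onset temperatures (K),
#'   from the empirical result.
#'
#' @param fits A single [fit_unfolding()] result or a list of them for the
#'   same sample (one per model).
#' @param tref Reference temperature for extrapolation, kelvin.
#' @return One-row data frame of class `stability_record` with columns
#'   `sample_id`, `model`s contributing, measures, `Tm`, `Tonset`, `dHm`,
#'   `Ea`, `Tf`, `sd_Tm`, `S`, `BS` (worst of the contributing fits is *not*
#'   taken: thermodynamic values are reported) and `flags`
#'   (comma-separated).
#' @export
stability_measures <- function(fits, tref = .Tref_std) {
  if (inherits(fits, "unfold_fit")) fits <- list(fits)
  rec <- data.frame(sample_id = fits[[1]]$curve$sample_id,
                    dG_std = NA_real_, pku_std = NA_real_, Teucl = NA_real_,
                    Tm = NA_real_, Tonset = NA_real_, dHm = NA_real_,
                    Ea = NA_real_, Tf = NA_real_, sd_Tm = NA_real_,
                    S = NA_real_, BS = NA_real_, flags = "",
                    stringsAsFactors = FALSE)
  flags <- character(0)
  for (f in fits) {
    flags <- union(flags, f$flags)
    if (is.null(f$par)) next
    if (f$model %in% c("thermodynamic", "empirical")) {
      rec$dG_std <- gibbs_free_energy(tref, f$par[["dHm"]], f$par[["Tm"]], f$dCp)
      rec$Tm <- f$par[["Tm"]]
      rec$dHm <- f$par[["dHm"]]
      rec$sd_Tm <- f$sd[["Tm"]]
      rec$S <- f$S
      rec$BS <- f$BS
    }
    if (f$model == "empirical") {
      rec$Tonset <- f$Tonset
      rec$Teucl <- f$Teucl
    }
    if (f$model == "kinetic") {
      rec$pku_std <- pku_std(f$par[["Ea"]], f$par[["Tf"]])
      rec$Ea <- f$par[["Ea"]]
      rec$Tf <- f$par[["Tf"]]
      if (is.na(rec$sd_Tm)) rec$sd_Tm <- f$sd[["Tf"]]
      if (is.na(rec$BS)) rec$BS <- f$BS
      if (is.na(rec$S)) rec$S <- f$S
    }
  }
  rec$flags <- paste(flags, collapse = ",")
  class(rec) <- c("stability_record", "data.frame")
  rec
}

#' Free-energy difference between a sample and a reference
#'
#' Signed difference `sample$dG_std - reference$dG_std` in J/mol; positive
#' when the sample is more stable than the reference.
#'
#' @param sample,reference `stability_record` rows with `dG_std` present.
#' @return ddG in J/mol.
#' @export
ddg <- function(sample, reference) {
  if (is.na(sample$dG_std) || is.na(reference$dG_std))
    stop("dG_std missing in sample or reference")
  sample$dG_std - reference$dG_std
}

#' Pairwise correlation of the three ranking measures
#'
#' Pearson and Kendall (tau-b) correlation matrices over `dG_std`,
#' `pku_std` and `Teucl` across samples.  High values mean the equilibrium,
#' kinetic and empirical descriptions rank the screen consistently.
#'
#' @param records Stability table (data frame with the three measure
#'   columns); rows with any missing measure are dropped.
#' @param min_records Minimum complete rows required (default 10).
#' @return List with elements `pearson` and `kendall` (3x3 matrices,
#'   unit diagonal) and `n` (rows used).
#' @export
measure_correlation <- function(records, min_records = 10L) {
  m <- as.data.frame(records)[, c("dG_std", "pku_std", "Teucl")]
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < min_records)
    stop(sprintf("need at least %d records with all three measures", min_records))
  for (nm in names(m))
    if (sd(m[[nm]]) == 0)
      stop(sprintf("measure '%s' is constant; correlation undefined", nm))
  list(pearson = cor(m, method = "pearson"),
       kendall = cor(m, method = "kendall"),
       n = nrow(m))
}

#' Aggregate a stability measure onto the plate layout
#'
#' Builds the heatmap table behind plate visualizations: one cell per
#' replicate group with the mean, SD and n of the chosen measure.  Failed
#' wells (measure missing) stay `NA` and are listed in the `missing`
#' attribute.  Row order follows the layout file order.
#'
#' @param records Stability table.
#' @param layout A [plate_layout()] covering the records.
#' @param measure Column to aggregate (default `"dG_std"`).
#' @return Data frame of class `heatmap_table` with columns
#'   `condition_label`, `replicate_group`, `mean`, `sd`, `n`, `wells`;
#'   attribute `measure` records the measure name.
#' @export
heatmap_table <- function(records, layout, measure = "dG_std") {
  df <- as.data.frame(records)
  if (!measure %in% names(df)) stop(sprintf("unknown measure '%s'", measure))
  if (all(is.na(df[[measure]])))
    stop(sprintf("measure '%s' absent in all records", measure))
  lay <- as.data.frame(layout)
  merged <- merge(lay, df[, c("sample_id", measure)], by = "sample_id",
                  all.x = TRUE, sort = FALSE)
  ## preserve layout order
  merged <- merged[match(lay$sample_id, merged$sample_id), ]
  groups <- unique(merged$replicate_group)
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- merged[merged$replicate_group == g, ]
    v <- sub[[measure]]
    data.frame(condition_label = sub$condition_label[1], replicate_group = g,
               mean = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
               sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else NA_real_,
               n = sum(!is.na(v)), wells = paste(sub$well, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  attr(out, "missing") <- out$replicate_group[is.na(out$mean)]
  class(out) <- c("heatmap_table", "data.frame")
  out
}

#' Render a plate heatmap
#'
#' Draws the 96-well (or configured) grid colored by the aggregated measure;
#' failed wells are shown as grey crosses.  The color scale spans the
#' observed minimum to maximum of the measure.
#'
#' @param records Stability table.
#' @param layout A [plate_layout()].
#' @param measure Measure column to display.
#' @param path Optional output path; its extension (`.png` or `.svg`)
#'   selects the device.  `NULL` draws on the active device.
#' @param grid_rows,grid_cols Plate geometry.
#' @return The [heatmap_table()] used, invisibly.
#' @export
plot_stability_heatmap <- function(records, layout, measure = "dG_std",
                                   path = NULL, grid_rows = LETTERS[1:8],
                                   grid_cols = 1:12) {
  ht <- heatmap_table(records, layout, measure)
  df <- as.data.frame(records)
  lay <- as.data.frame(layout)
  merged <- merge(lay, df[, c("sample_id", measure)], by = "sample_id",
                  all.x = TRUE, sort = FALSE)
  val <- merged[[measure]]
  rowi <- match(substr(merged$well, 1, 1), grid_rows)
  coli <- as.integer(sub("^[A-Za-z]", "", merged$well))
  if (!is.null(path)) {
    if (grepl("\\.svg$", path)) svg(path, width = 8, height = 5.5)
    else png(path, width = 960, height = 660, res = 110)
    on.exit(dev.off(), add = TRUE)
  }
  pal <- colorRampPalette(c("#313695", "#ffffbf", "#a50026"))(100)
  rngv <- range(val, na.rm = TRUE)
  colidx <- if (diff(rngv) == 0) rep(50L, length(val)) else
    pmax(1L, pmin(100L, 1L + as.integer(99 * (val - rngv[1]) / diff(rngv))))
  op <- par(mar = c(4, 4, 3, 1))
  on.exit(par(op), add = TRUE)
  plot(NA, xlim = c(0.5, length(grid_cols) + 0.5),
       ylim = c(length(grid_rows) + 0.5, 0.5), xlab = "Column", ylab = "Row",
       axes = FALSE, main = sprintf("%s heatmap", measure))
  axis(1, at = seq_along(grid_cols), labels = grid_cols)
  axis(2, at = seq_along(grid_rows), labels = grid_rows, las = 1)
  box()
  for (i in seq_along(val)) {
    if (is.na(val[i])) {
      rect(coli[i] - 0.45, rowi[i] - 0.45, coli[i] + 0.45, rowi[i] + 0.45,
           col = "grey85", border = "grey60")
      text(coli[i], rowi[i], "x", col = "grey50")
    } else {
      rect(coli[i] - 0.45, rowi[i] - 0.45, coli[i] + 0.45, rowi[i] + 0.45,
           col = pal[colidx[i]], border = "grey40")
    }
  }
  mtext(sprintf("scale: %.4g to %.4g", rngv[1], rngv[2]), side = 3,
        line = 0.2, cex = 0.8)
  invisible(ht)
}
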