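## Input/output for multi-sample unfolding data and plate metadata.
##
## Canonical input is a wide table: first column is temperature, every further
## column one sample.  Temperatures are stored in kelvin everywhere inside the
## package; degrees Celsius appear only at the I/O boundary and only when
## explicitly requested.

#' Construct a melting curve
#'
#' A `melting_curve` holds one sample's signal versus temperature together
#' with the readout label, the temperature scan rate and the preprocessing
#' history.  Temperatures are kelvin, strictly increasing; the signal is in
#' arbitrary units (fluorescence counts, F350/F330 ratio, CD millidegrees...).
#'
#' @param temperature Numeric vector of temperatures in kelvin, strictly
#'   increasing.
#' @param signal Numeric vector of the same length, no missing values.
#' @param sample_id Sample identifier.
#' @param readout One of `"F330"`, `"F350"`, `"ratio"`, `"CD"`, `"generic"`.
#' @param scan_rate Temperature scan rate in K/min (default 1, the usual
#'   setting of capillary-based intrinsic-fluorescence instruments).
#' @param history List of preprocessing step descriptors (created internally).
#' @param min_points Minimum number of retained points (default 20).
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperature, signal, sample_id = "sample",
                          readout = c("generic", "F330", "F350", "ratio", "CD"),
                          scan_rate = 1.0, history = list(), min_points = 20L) {
  readout <- match.arg(readout)
  temperature <- as.numeric(temperature)
  signal <- as.numeric(signal)
  if (length(temperature) != length(signal))
    stop("temperature and signal must have the same length")
  keep <- is.finite(temperature) & is.finite(signal)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    temperature <- temperature[keep]
    signal <- signal[keep]
    history <- c(history, list(list(step = "drop_na", n_dropped = n_dropped)))
  }
  if (length(temperature) < min_points)
    stop(sprintf("melting curve '%s' has %d points; at least %d required",
                 sample_id, length(temperature), min_points))
  if (any(diff(temperature) <= 0))
    stop("nonmonotonic temperature")
  if (!is.numeric(scan_rate) || scan_rate <= 0)
    stop("scan_rate must be > 0 (K/min)")
  structure(
    list(sample_id = as.character(sample_id), readout = readout,
         temperature = temperature, signal = signal,
         scan_rate = scan_rate, history = history),
    class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("Melting curve '%s' (%s readout)\n", x$sample_id, x$readout))
  cat(sprintf("  %d points, %.2f-%.2f K, scan rate %.2g K/min\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              x$scan_rate))
  if (length(x$history))
    cat("  preprocessing:", paste(vapply(x$history, `[[`, "", "step"),
                                  collapse = " -> "), "\n")
  invisible(x)
}

#' @export
plot.melting_curve <- function(x, ...) {
  plot(x$temperature, x$signal, xlab = "Temperature (K)",
       ylab = sprintf("Signal (%s)", x$readout), main = x$sample_id,
       pch = 16, cex = 0.5, ...)
  invisible(x)
}

## median temperature step of a curve, K
.median_step <- function(curve) median(diff(curve$temperature))

.append_history <- function(curve, step, ...) {
  curve$history <- c(curve$history, list(c(list(step = step), list(...))))
  curve
}

#' Read multi-sample unfolding curves from a wide table
#'
#' The expected layout is a header row followed by one temperature column and
#' one column per sample (`temperature,<id1>,<id2>,...`).  Columns with fewer
#' than `min_points` finite readings are skipped with a per-sample warning;
#' interior missing points are dropped (not interpolated) and the count is
#' recorded in the curve history.
#'
#' @param path Path to a CSV or XLSX file.
#' @param format `"csv"` (default) or `"xlsx"` (first sheet; requires the
#'   readxl package).
#' @param temperature_unit `"celsius"` (converted to kelvin as T + 273.15) or
#'   `"kelvin"`.  Input units are never guessed.
#' @param readout Readout label attached to every curve.
#' @param scan_rate Scan rate in K/min attached to every curve.
#' @param min_points Minimum finite points per usable sample (default 20).
#' @return Named list of [melting_curve] objects.
#' @export
read_curves <- function(path, format = c("csv", "xlsx"),
                        temperature_unit = c("celsius", "kelvin"),
                        readout = "generic", scan_rate = 1.0,
                        min_points = 20L) {
  format <- match.arg(format)
  temperature_unit <- match.arg(temperature_unit)
  tab <- switch(format,
    csv = read.csv(path, check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the 'readxl' package")
      as.data.frame(readxl::read_excel(path, sheet = 1))
    })
  if (ncol(tab) < 2) stop("input table needs a temperature column and at least one sample")
  temp <- as.numeric(tab[[1]])
  if (any(!is.finite(temp))) stop("temperature column contains non-numeric values")
  if (any(diff(temp) <= 0)) stop("nonmonotonic temperature")
  if (temperature_unit == "celsius") temp <- temp + 273.15
  ids <- names(tab)[-1]
  if (anyDuplicated(ids)) stop("duplicate sample IDs in header")
  curves <- list()
  for (id in ids) {
    y <- as.numeric(tab[[id]])
    if (sum(is.finite(y)) < min_points) {
      warning(sprintf("sample '%s' unreadable (<%d finite points); skipped",
                      id, min_points), call. = FALSE)
      next
    }
    curves[[id]] <- melting_curve(temp, y, sample_id = id, readout = readout,
                                  scan_rate = scan_rate,
                                  min_points = min_points)
  }
  curves
}

#' Write a stability results table
#'
#' One row per sample with fitted parameters, their standard deviations, the
#' standard error of estimate, the baseline-separation factor, the ranking
#' measures and quality flags.  Values survive a CSV round trip to at least
#' six significant digits.
#'
#' @param records A `stability_table` (data frame) as produced by
#'   [stability_measures()] / [run_screen()].
#' @param path Output path.
#' @param format Only `"csv"` is supported for export; `"xlsx"` stops with an
#'   informative error (no spreadsheet writer is bundled).
#' @export
write_results <- function(records, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (is.null(records) || nrow(as.data.frame(records)) == 0)
    stop("records must be nonempty")
  if (format == "xlsx")
    stop("xlsx export is not supported; use format = 'csv' (readable by any spreadsheet program)")
  df <- as.data.frame(records)
  ## full precision so a round trip reproduces values to >= 6 significant digits
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a stability results table written by [write_results()]
#' @param path Path to the CSV file.
#' @return Data frame with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  for (j in seq_along(df)) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    introduced_na <- is.na(x) & !is.na(df[[j]])
    if (!any(introduced_na)) df[[j]] <- x
  }
  df
}

#' Read a plate layout
#'
#' Layout CSV columns: `sample_id`, `well`, `condition_label` and optionally
#' `replicate_group` (defaults to the sample id) and `is_reference`
#' (true/false, at most one reference per comparison set).
#'
#' @param path Path to the layout CSV.
#' @param grid_rows,grid_cols Plate grammar; defaults to rows `A`-`H` and
#'   columns 1-12 (a 96-well plate).
#' @return A data frame of class `plate_layout`.
#' @export
read_layout <- function(path, grid_rows = LETTERS[1:8], grid_cols = 1:12) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  req <- c("sample_id", "well", "condition_label")
  if (!all(req %in% names(df)))
    stop("layout must have columns sample_id, well, condition_label")
  plate_layout(sample_id = df$sample_id, well = df$well,
               condition_label = df$condition_label,
               replicate_group = if ("replicate_group" %in% names(df)) df$replicate_group else NULL,
               is_reference = if ("is_reference" %in% names(df)) df$is_reference else NULL,
               grid_rows = grid_rows, grid_cols = grid_cols)
}

#' Construct a plate layout
#'
#' @param sample_id Character vector of unique sample ids.
#' @param well Well ids such as `"A1"`..`"H12"`.
#' @param condition_label Condition description per sample.
#' @param replicate_group Replicate grouping; missing or empty entries default
#'   to the sample id.
#' @param is_reference Logical (or "true"/"false" strings); at most one
#'   reference per replicate comparison set.
#' @param grid_rows,grid_cols Allowed well grammar.
#' @return Data frame of class `plate_layout`.
#' @export
plate_layout <- function(sample_id, well, condition_label,
                         replicate_group = NULL, is_reference = NULL,
                         grid_rows = LETTERS[1:8], grid_cols = 1:12) {
  n <- length(sample_id)
  if (anyDuplicated(sample_id))
    stop("sample_ids must be unique in a plate layout")
  if (is.null(replicate_group)) replicate_group <- sample_id
  replicate_group <- ifelse(is.na(replicate_group) | replicate_group == "",
                            sample_id, replicate_group)
  if (is.null(is_reference)) is_reference <- rep(FALSE, n)
  if (is.character(is_reference))
    is_reference <- tolower(is_reference) %in% c("true", "t", "1", "yes")
  valid <- paste0(rep(grid_rows, each = length(grid_cols)),
                  rep(grid_cols, length(grid_rows)))
  bad <- which(!(well %in% valid))
  if (length(bad))
    stop(sprintf("malformed well ID '%s' in layout row %d", well[bad[1]], bad[1]))
  nref <- tapply(is_reference, replicate_group, sum)
  if (any(nref > 1))
    stop("at most one is_reference per replicate group")
  structure(
    data.frame(sample_id = sample_id, well = well,
               condition_label = condition_label,
               replicate_group = replicate_group,
               is_reference = is_reference,
               stringsAsFactors = FALSE),
    class = c("plate_layout", "data.frame"))
}

#' Write a plate layout CSV
#' @param layout A [plate_layout()].
#' @param path Output path.
#' @export
write_layout <- function(layout, path) {
  write.csv(as.data.frame(layout), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
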