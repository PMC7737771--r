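## Curve "rescue" preprocessing and derivative/baseline estimation.
##
## All windows are stated in kelvin and converted to odd point counts via the
## median temperature step, because the smoothing filters operate on points
## while instrument settings are naturally expressed in K.

## convert a kelvin window to an odd point count given a step size
.window_points <- function(window_k, step, minimum = 3L) {
  n <- max(minimum, round(window_k / step))
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  n
}

#' Trim a melting curve to a temperature window
#'
#' Removes points at the start or end of a scan, e.g. to cut off condensation
#' artifacts or a second transition.
#'
#' @param curve A [melting_curve()].
#' @param t_low,t_high Window bounds in kelvin (`t_low < t_high`).
#' @return The trimmed curve with the step recorded in its history.
#' @export
trim_curve <- function(curve, t_low, t_high) {
  stopifnot(inherits(curve, "melting_curve"))
  if (t_low >= t_high) stop("t_low must be below t_high")
  keep <- curve$temperature >= t_low & curve$temperature <= t_high
  if (sum(keep) < 20) stop("over-trimmed: fewer than 20 points remain")
  curve$temperature <- curve$temperature[keep]
  curve$signal <- curve$signal[keep]
  .append_history(curve, "trim", t_low = t_low, t_high = t_high)
}

#' Median-filter a melting curve
#'
#' Running median smoothing to suppress single-point spikes; the window is
#' given in kelvin and converted to an odd number of points.
#'
#' @param curve A [melting_curve()].
#' @param window_k Filter window in kelvin (default 2 K).
#' @return Smoothed curve, same length.
#' @export
smooth_median <- function(curve, window_k = 2.0) {
  stopifnot(inherits(curve, "melting_curve"))
  k <- .window_points(window_k, .median_step(curve))
  if (k < 3) stop("median filter window below 3 points")
  if (k >= length(curve$signal)) stop("median filter window exceeds curve length")
  curve$signal <- as.numeric(stats::runmed(curve$signal, k, endrule = "median"))
  .append_history(curve, "smooth_median", window_k = window_k, points = k)
}

#' Bin a melting curve
#'
#' Averages temperature and signal within consecutive temperature bins to
#' suppress noise and expose trends; empty bins are dropped.
#'
#' @param curve A [melting_curve()].
#' @param bin_width Bin width in kelvin; must be at least twice the median
#'   temperature step.
#' @return Binned curve (per-bin mean temperature and mean signal).
#' @export
bin_curve <- function(curve, bin_width) {
  stopifnot(inherits(curve, "melting_curve"))
  step <- .median_step(curve)
  if (bin_width < 2 * step)
    stop("bin_width must be at least twice the median temperature step")
  tt <- curve$temperature
  edges <- seq(min(tt), max(tt) + bin_width, by = bin_width)
  idx <- findInterval(tt, edges, rightmost.closed = TRUE)
  tm <- tapply(tt, idx, mean)
  sm <- tapply(curve$signal, idx, mean)
  if (length(tm) < 20) stop("fewer than 20 bins; decrease bin_width")
  curve$temperature <- as.numeric(tm)
  curve$signal <- as.numeric(sm)
  .append_history(curve, "bin", bin_width = bin_width)
}

#' Savitzky-Golay first derivative of a melting curve
#'
#' Least-squares local polynomial derivative estimate; exact for polynomial
#' signals up to the filter order.  Used to initialize the melting temperature
#' from the derivative extremum.
#'
#' @param curve A [melting_curve()].
#' @param window_k Window size in kelvin (default 10 K), converted to an odd
#'   point count via the median step.
#' @param polyorder Polynomial order (default 4).
#' @return Numeric vector of dSignal/dT (units/K), same length as the curve.
#' @export
savgol_derivative <- function(curve, window_k = 10.0, polyorder = 4L) {
  stopifnot(inherits(curve, "melting_curve"))
  step <- .median_step(curve)
  n <- .window_points(window_k, step, minimum = polyorder + 2L)
  if (n %% 2L == 0L) n <- n + 1L
  if (n <= polyorder) stop("window too small for the requested polynomial order")
  if (n > length(curve$signal)) stop("too few points for the derivative window")
  as.numeric(signal::sgolayfilt(curve$signal, p = polyorder, n = n, m = 1,
                                ts = step))
}

#' Estimate curve shape, baselines and an initial melting temperature
#'
#' Fits straight lines to the first and last 10 K of the scan (the native and
#' unfolded baselines), classifies the curve as S-shaped (signal rises with
#' temperature) or Z-shaped (signal falls) by comparing the two lines at the
#' scan midpoint, and takes the global extremum of the Savitzky-Golay
#' derivative between the two baseline stretches as the initial melting
#' temperature (maximum for S curves, minimum for Z; ties broken toward lower
#' temperature).  Curves whose derivative extremum is indistinguishable from
#' derivative noise (below `flat_mad_factor` times the derivative MAD) are
#' flagged `"no transition"` and given the scan midpoint as a placeholder.
#'
#' @param curve A [melting_curve()].
#' @param stretch_k Baseline stretch length in kelvin (default 10 K).
#' @param window_k,polyorder Passed to [savgol_derivative()].
#' @param flat_mad_factor Flat-curve threshold (default 3).
#' @return A list of class `curve_shape` with elements `kind` ("S"/"Z"),
#'   `kN`, `bN`, `kU`, `bU` (baseline slopes/intercepts), `tm_initial`,
#'   `deriv_height` (peak |d fraction/dT| estimate, 1/K) and `flags`.
#' @export
estimate_shape <- function(curve, stretch_k = 10.0, window_k = 10.0,
                           polyorder = 4L, flat_mad_factor = 3.0) {
  stopifnot(inherits(curve, "melting_curve"))
  tt <- curve$temperature
  yy <- curve$signal
  rng <- range(tt)
  if (diff(rng) < 3 * stretch_k)
    stop("scan too short for baseline estimation")
  pre <- tt <= rng[1] + stretch_k
  post <- tt >= rng[2] - stretch_k
  fit_pre <- lm(yy[pre] ~ tt[pre])
  fit_post <- lm(yy[post] ~ tt[post])
  kN <- unname(coef(fit_pre)[2]); bN <- unname(coef(fit_pre)[1])
  kU <- unname(coef(fit_post)[2]); bU <- unname(coef(fit_post)[1])
  tmid <- mean(rng)
  kind <- if (kU * tmid + bU >= kN * tmid + bN) "S" else "Z"
  deriv <- savgol_derivative(curve, window_k = window_k, polyorder = polyorder)
  interior <- !pre & !post
  flags <- character(0)
  if (!any(interior)) interior <- rep(TRUE, length(tt))
  d_int <- deriv[interior]; t_int <- tt[interior]
  i_ext <- if (kind == "S") which.max(d_int) else which.min(d_int)
  ext_val <- d_int[i_ext]
  ## a transition shows up as a *peak* relative to the bulk derivative level;
  ## compare the centered extremum against the derivative noise MAD (with a
  ## floating-point floor so numerically constant curves register as flat)
  noise <- mad(deriv)
  peak <- abs(ext_val - median(deriv))
  eps <- 1e-8 * (max(abs(yy)) + 1) / diff(rng)
  if (peak <= flat_mad_factor * noise + eps) {
    flags <- c(flags, "no_transition")
    tm_initial <- tmid
  } else {
    tm_initial <- t_int[i_ext]
  }
  sep_at_tm <- abs((kU - kN) * tm_initial + (bU - bN))
  deriv_height <- if (sep_at_tm > 0) abs(ext_val) / sep_at_tm else NA_real_
  structure(list(kind = kind, kN = kN, bN = bN, kU = kU, bU = bU,
                 tm_initial = tm_initial, deriv_height = deriv_height,
                 flags = flags),
            class = "curve_shape")
}

#' @export
print.curve_shape <- function(x, ...) {
  cat(sprintf("%s-shaped curve, initial Tm %.2f K%s\n", x$kind, x$tm_initial,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  cat(sprintf("  native baseline:   %.4g * T + %.4g\n", x$kN, x$bN))
  cat(sprintf("  unfolded baseline: %.4g * T + %.4g\n", x$kU, x$bU))
  invisible(x)
}
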