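## Synthetic unfolding data with known ground truth.
##
## Defaults emulate a capillary fluorescence-ratio thermal scan: temperature
## 293.15-368.15 K (20-95 C) in 0.5 K steps at 1 K/min, pretransition ratio
## ~0.8 and posttransition ~0.95 with small positive slopes, homoscedastic
## Gaussian noise.

#' Default ratio-like baseline parameters
#'
#' Pretransition level ~0.8 and posttransition ~0.95 at the start of the
#' scan with small positive slopes, mimicking F350/F330 ratio curves.
#'
#' @param t0 Temperature at which the levels are anchored, kelvin.
#' @return Named vector `kN`, `bN`, `kU`, `bU`.
#' @export
default_baselines <- function(t0 = 293.15) {
  kN <- 2e-4; kU <- 5e-4
  c(kN = kN, bN = 0.8 - kN * t0, kU = kU, bU = 0.95 - kU * t0)
}

#' Simulate one melting curve
#'
#' Forward-evaluates the chosen model and adds homoscedastic Gaussian noise.
#' With `noise_sd = 0` the curve equals the forward model exactly.  The
#' generating parameters are attached as attribute `truth` for recovery
#' tests.
#'
#' @param model `"thermodynamic"` or `"kinetic"`.
#' @param params Named vector with baselines `kN`, `bN`, `kU`, `bU` and the
#'   core pair (`dHm`, `Tm` or `Ea`, `Tf`).
#' @param T_grid Temperature grid, kelvin.
#' @param noise_sd Gaussian noise SD, signal units.
#' @param seed Optional RNG seed (fixed seed gives identical output).
#' @param scan_rate Scan rate, K/min.
#' @param sample_id,readout Curve labels.
#' @param dCp Fixed heat-capacity change for the thermodynamic model.
#' @param truncate_at If not `NULL`, the scan is cut where the model's
#'   fraction unfolded first exceeds this value (e.g. 0.6), emulating a
#'   protein whose unfolding is incomplete within the temperature range: the
#'   posttransition baseline is missing and only the derivative-peak melting
#'   temperature is meaningful.
#' @return A [melting_curve()] with attribute `truth`.
#' @export
simulate_curve <- function(model = c("thermodynamic", "kinetic"),
                           params,
                           T_grid = seq(293.15, 368.15, by = 0.5),
                           noise_sd = 0, seed = NULL, scan_rate = 1.0,
                           sample_id = "sim", readout = "ratio", dCp = 0,
                           truncate_at = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  y <- if (model == "thermodynamic") equilibrium_signal(T_grid, params, dCp)
       else kinetic_signal(T_grid, params, scan_rate)
  if (!is.null(truncate_at)) {
    f <- if (model == "thermodynamic")
      .f_unfolded(T_grid, as.list(params)$dHm, as.list(params)$Tm, dCp)
    else 1 - kinetic_xn(T_grid, as.list(params)$Ea, as.list(params)$Tf, scan_rate)
    cut <- which(f > truncate_at)
    if (length(cut)) {
      T_grid <- T_grid[seq_len(cut[1])]
      y <- y[seq_len(cut[1])]
    }
  }
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  cv <- melting_curve(T_grid, y, sample_id = sample_id, readout = readout,
                      scan_rate = scan_rate)
  attr(cv, "truth") <- c(params, dCp = dCp)
  cv
}

#' Simulate a panel of melting curves
#'
#' Generates `n` curves with known ground truth.  Two panel families:
#'
#' * `"kirchhoff"` (default): one melting unit measured across conditions.
#'   Melting temperatures are uniform over `tm_range` and the enthalpy
#'   follows the heat-capacity (Kirchhoff) line through the range ends,
#'   `dHm = dhm_range[1] + slope * (Tm - tm_range[1])`, with multiplicative
#'   scatter `dhm_scatter` -- the covariance structure of a real
#'   single-protein screen, where enthalpy and melting temperature co-vary.
#' * `"independent"`: enthalpy and melting temperature drawn independently;
#'   useful for parameter-recovery sweeps but not representative of a
#'   condition screen.
#'
#' Noise is homoscedastic Gaussian with SD equal to `noise` times the
#' baseline separation (transition height) at the scan midpoint.
#'
#' @param n Number of curves.
#' @param seed RNG seed (the panel is reproducible byte for byte).
#' @param model `"thermodynamic"` or `"kinetic"` generating model.
#' @param tm_range Range of midpoint temperatures, kelvin.
#' @param dhm_range Range of enthalpies (or activation energies), J/mol.
#' @param family `"kirchhoff"` or `"independent"`.
#' @param dhm_scatter Relative scatter of the enthalpy about the Kirchhoff
#'   line (default 0.05, the typical replicate-level relative error of
#'   enthalpy estimates).
#' @param noise Noise SD as a fraction of the transition height
#'   (default 0.01).
#' @param T_grid Temperature grid.
#' @param baselines Baseline parameters, see [default_baselines()].
#' @param scan_rate Scan rate, K/min.
#' @return List with `curves` (list of [melting_curve()]) and `truth`
#'   (data frame of generating parameters).
#' @export
simulate_panel <- function(n = 40, seed = 1,
                           model = c("thermodynamic", "kinetic"),
                           tm_range = c(300, 360),
                           dhm_range = c(1e5, 1e6),
                           family = c("kirchhoff", "independent"),
                           dhm_scatter = 0.05, noise = 0.01,
                           T_grid = seq(293.15, 368.15, by = 0.5),
                           baselines = default_baselines(),
                           scan_rate = 1.0) {
  model <- match.arg(model)
  family <- match.arg(family)
  set.seed(seed)
  Tm <- runif(n, tm_range[1], tm_range[2])
  dHm <- switch(family,
    kirchhoff = {
      slope <- diff(dhm_range) / diff(tm_range)
      (dhm_range[1] + slope * (Tm - tm_range[1])) *
        (1 + rnorm(n, 0, dhm_scatter))
    },
    independent = runif(n, dhm_range[1], dhm_range[2]))
  tmid <- mean(range(T_grid))
  height <- abs((baselines[["kU"]] - baselines[["kN"]]) * tmid +
                (baselines[["bU"]] - baselines[["bN"]]))
  noise_sd <- noise * height
  curves <- vector("list", n)
  ids <- sprintf("s%02d", seq_len(n))
  for (i in seq_len(n)) {
    params <- if (model == "thermodynamic")
      c(baselines, dHm = dHm[i], Tm = Tm[i])
    else c(baselines, Ea = dHm[i], Tf = Tm[i])
    curves[[i]] <- simulate_curve(model, params, T_grid = T_grid,
                                  noise_sd = noise_sd, scan_rate = scan_rate,
                                  sample_id = ids[i])
  }
  names(curves) <- ids
  truth <- data.frame(sample_id = ids, Tm = Tm, dHm = dHm,
                      noise_sd = noise_sd, stringsAsFactors = FALSE)
  if (model == "kinetic") names(truth)[2:3] <- c("Tf", "Ea")
  list(curves = curves, truth = truth)
}

#' Write a simulated screen as canonical input files
#'
#' Emits the wide curves CSV (`temperature,<id1>,...`, temperatures in
#' kelvin) and the matching layout CSV so that a full screen analysis can be
#' exercised end to end without instrument data.
#'
#' @param panel Result of [simulate_panel()].
#' @param layout A [plate_layout()] with exactly one entry per panel curve,
#'   or `NULL` to fabricate a row-major plate layout.
#' @param curves_path,layout_path Output paths.
#' @return Named character vector with the two paths.
#' @export
simulate_screen <- function(panel, layout = NULL,
                            curves_path = tempfile(fileext = ".csv"),
                            layout_path = tempfile(fileext = ".csv")) {
  curves <- panel$curves
  n <- length(curves)
  if (is.null(layout)) {
    wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))[seq_len(n)]
    layout <- plate_layout(sample_id = names(curves), well = wells,
                           condition_label = paste("condition", seq_len(n)))
  }
  if (nrow(layout) != n)
    stop("layout size must equal the number of simulated curves")
  tt <- curves[[1]]$temperature
  for (cv in curves)
    if (!identical(cv$temperature, tt))
      stop("all curves must share one temperature grid to share a file")
  tab <- data.frame(temperature = tt, check.names = FALSE)
  for (id in names(curves)) tab[[id]] <- curves[[id]]$signal
  write.csv(tab, curves_path, row.names = FALSE, quote = FALSE)
  write_layout(layout, layout_path)
  c(curves = curves_path, layout = layout_path)
}
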