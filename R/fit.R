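## Bounded nonlinear least-squares fitting of unfolding models to a curve.
##
## Strategy: baseline and shape estimates seed a two-stage Levenberg-
## Marquardt fit (stage 1 refines the two core parameters with the baselines
## held at their stretch estimates, stage 2 releases all six).  The staged
## start makes the fit robust for steep transitions where a one-shot fit from
## the generic enthalpy start value can stall with the midpoint pinned at a
## bound.  Fitting is fully deterministic.

#' Fitting configuration
#'
#' @param max_iter Maximum Levenberg-Marquardt iterations per stage.
#' @param dHm_init Start value for the unfolding enthalpy, J/mol
#'   (default 100,000).
#' @param dHm_bounds Bounds for the enthalpy, J/mol (default 60 kJ to 4 MJ).
#' @param Ea_bounds Bounds for the kinetic activation energy, J/mol.
#' @param sd_tm_max Reliability threshold on SD(Tm)/SD(Tf) in kelvin; fits
#'   above it are flagged `unreliable_tm_sd` (default 0.5 K).
#' @param onset_fraction Fraction unfolded defining the onset temperature.
#' @param stretch_k,savgol_window_k,savgol_polyorder,flat_mad_factor Passed
#'   to [estimate_shape()].
#' @param bs_threshold,bs_margin Readout-selection rule parameters, see
#'   [select_readout()].
#' @return List of class `fit_control`.
#' @export
fit_control <- function(max_iter = 500L,
                        dHm_init = 1e5,
                        dHm_bounds = c(6e4, 4e6),
                        Ea_bounds = c(1e4, 4e6),
                        sd_tm_max = 0.5,
                        onset_fraction = 0.01,
                        stretch_k = 10.0,
                        savgol_window_k = 10.0,
                        savgol_polyorder = 4L,
                        flat_mad_factor = 3.0,
                        bs_threshold = 0.25,
                        bs_margin = 0.1) {
  structure(list(max_iter = max_iter, dHm_init = dHm_init,
                 dHm_bounds = dHm_bounds, Ea_bounds = Ea_bounds,
                 sd_tm_max = sd_tm_max, onset_fraction = onset_fraction,
                 stretch_k = stretch_k, savgol_window_k = savgol_window_k,
                 savgol_polyorder = savgol_polyorder,
                 flat_mad_factor = flat_mad_factor,
                 bs_threshold = bs_threshold, bs_margin = bs_margin),
            class = "fit_control")
}

#' Baseline-separation factor
#'
#' Fit-quality score `BS = 1 - 6*S / |kU*Tm + bU - kN*Tm - bN|`, relating
#' the standard error of estimate to the distance between the extrapolated
#' baselines at the melting temperature.  The absolute value in the
#' denominator makes rising (S) and falling (Z) curves score identically.
#' Values between 0.5 and 1 indicate excellent separation; negative values an
#' unreliable curve.  A zero separation yields `-Inf`.
#'
#' @param S Standard error of estimate, signal units.
#' @param kN,bN,kU,bU Fitted baseline slopes and intercepts.
#' @param Tm Melting temperature, kelvin.
#' @return Dimensionless BS-factor (<= 1).
#' @export
bs_factor <- function(S, kN, bN, kU, bU, Tm) {
  sep <- abs(kU * Tm + bU - kN * Tm - bN)
  if (sep == 0) return(-Inf)
  1 - 6 * S / sep
}

## residual closure for a model given data
.resid_fun <- function(model, tt, yy, v) {
  if (model == "thermodynamic") {
    function(p) {
      names(p) <- c("kN", "bN", "kU", "bU", "dHm", "Tm")
      equilibrium_signal(tt, p) - yy
    }
  } else {
    function(p) {
      names(p) <- c("kN", "bN", "kU", "bU", "Ea", "Tf")
      kinetic_signal(tt, p, v) - yy
    }
  }
}

## two-stage bounded LM fit; returns nls.lm object of the final stage
.fit_two_stage <- function(resid, init, lower, upper, max_iter) {
  core <- function(p) resid(c(init[1:4], p))
  s1 <- minpack.lm::nls.lm(par = init[5:6], lower = lower[5:6],
                           upper = upper[5:6], fn = core,
                           control = minpack.lm::nls.lm.control(maxiter = max_iter))
  minpack.lm::nls.lm(par = c(init[1:4], s1$par), lower = lower, upper = upper,
                     fn = resid,
                     control = minpack.lm::nls.lm.control(maxiter = max_iter))
}

#' Fit an unfolding model to a melting curve
#'
#' Fits the equilibrium thermodynamic, irreversible kinetic, or empirical
#' model to one curve by bounded Levenberg-Marquardt least squares.
#'
#' Initialization: baselines from 10 K stretch fits ([estimate_shape()]);
#' melting temperature from the derivative extremum; enthalpy always started
#' at 100,000 J/mol.  For the kinetic model the activation energy is seeded
#' from the derivative peak height (matching midpoint slopes between the two
#' model families) and `Tf` from the corresponding midpoint condition.
#' Bounds: `Tm`/`Tf` within the scan range, `dHm` in 60-4,000 kJ/mol, `Ea`
#' in 10-4,000 kJ/mol, baselines unbounded.
#'
#' The empirical model is the thermodynamic fit augmented with the onset
#' temperature and the Euclidean measure; its `Tm` equals the thermodynamic
#' `Tm` exactly.
#'
#' Parameter standard deviations come from the square roots of the diagonal
#' of the covariance matrix `S^2 (J'J)^-1`; a singular Jacobian marks the fit
#' failed rather than guessing with a pseudo-inverse.  Fits with
#' `SD(Tm) > 0.5 K` are flagged `unreliable_tm_sd` but kept, so screens stay
#' auditable.
#'
#' @param curve A preprocessed [melting_curve()].
#' @param model `"thermodynamic"` (default), `"kinetic"` or `"empirical"`.
#' @param dCp Fixed heat-capacity change for the thermodynamic model, J/mol/K.
#' @param control A [fit_control()].
#' @return Object of class `unfold_fit` with components `model`, `par`
#'   (named: `kN`, `bN`, `kU`, `bU` and `dHm`, `Tm` or `Ea`, `Tf`), `sd`
#'   (matching SDs), `S` (standard error of estimate), `BS`
#'   (baseline-separation factor), `N`, `n_par`, `flags`, `curve`, `shape`,
#'   and for the empirical model `Tonset` and `Teucl`.  Methods: `print`,
#'   `summary`, `coef`, `vcov`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`.
#' @export
fit_unfolding <- function(curve,
                          model = c("thermodynamic", "kinetic", "empirical"),
                          dCp = 0, control = fit_control()) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "melting_curve"))
  tt <- curve$temperature
  yy <- curve$signal
  rng <- range(tt)

  shape <- estimate_shape(curve, stretch_k = control$stretch_k,
                          window_k = control$savgol_window_k,
                          polyorder = control$savgol_polyorder,
                          flat_mad_factor = control$flat_mad_factor)
  out <- structure(
    list(model = model, par = NULL, sd = NULL, S = NA_real_, BS = NA_real_,
         N = length(tt), n_par = 6L, flags = character(0), dCp = dCp,
         curve = curve, shape = shape, control = control),
    class = "unfold_fit")

  if ("no_transition" %in% shape$flags) {
    out$flags <- "no_transition"
    return(out)
  }

  base_init <- c(shape$kN, shape$bN, shape$kU, shape$bU)
  fit_model <- if (model == "kinetic") "kinetic" else "thermodynamic"
  if (fit_model == "thermodynamic") {
    init <- c(base_init, control$dHm_init, shape$tm_initial)
    lower <- c(rep(-Inf, 4), control$dHm_bounds[1], rng[1])
    upper <- c(rep(Inf, 4), control$dHm_bounds[2], rng[2])
    resid <- function(p) {
      names(p) <- c("kN", "bN", "kU", "bU", "dHm", "Tm")
      equilibrium_signal(tt, p, dCp) - yy
    }
    pnames <- c("kN", "bN", "kU", "bU", "dHm", "Tm")
  } else {
    ki <- .kinetic_init(shape, control, rng)
    init <- c(base_init, ki["Ea"], ki["Tf"])
    lower <- c(rep(-Inf, 4), control$Ea_bounds[1], rng[1])
    upper <- c(rep(Inf, 4), control$Ea_bounds[2], rng[2])
    resid <- .resid_fun("kinetic", tt, yy, curve$scan_rate)
    pnames <- c("kN", "bN", "kU", "bU", "Ea", "Tf")
  }

  fit <- tryCatch(.fit_two_stage(resid, init, lower, upper, control$max_iter),
                  error = function(e) NULL)
  if (is.null(fit) || fit$info == 0 || fit$info == 5) {
    out$flags <- "fit_failed"
    return(out)
  }
  par <- setNames(as.numeric(fit$par), pnames)
  S2 <- fit$deviance / (out$N - out$n_par)
  cov <- tryCatch(S2 * chol2inv(chol(fit$hessian)), error = function(e) NULL)
  if (is.null(cov)) {
    out$flags <- "fit_failed"
    return(out)
  }
  out$par <- par
  out$sd <- setNames(sqrt(pmax(diag(cov), 0)), pnames)
  out$cov <- cov
  out$S <- sqrt(S2)
  tm_like <- par[[if (fit_model == "thermodynamic") "Tm" else "Tf"]]
  out$BS <- bs_factor(out$S, par[["kN"]], par[["bN"]], par[["kU"]],
                      par[["bU"]], tm_like)
  if (!is.finite(out$BS)) out$flags <- c(out$flags, "no_transition")
  sd_tm <- out$sd[[if (fit_model == "thermodynamic") "Tm" else "Tf"]]
  if (is.finite(sd_tm) && sd_tm > control$sd_tm_max)
    out$flags <- c(out$flags, "unreliable_tm_sd")

  if (model == "empirical") {
    To <- t_onset(par[["dHm"]], par[["Tm"]], dCp,
                  onset_fraction = control$onset_fraction,
                  t_scan_min = rng[1])
    if (isTRUE(attr(To, "extrapolated")))
      out$flags <- c(out$flags, "onset_extrapolated")
    out$Tonset <- as.numeric(To)
    out$Teucl <- t_eucl(par[["Tm"]], out$Tonset)
  }
  out
}

## kinetic start values from the derivative peak height h (1/K):
## matching the midpoint slope of the kinetic family, x'(mid) ~ ln2/2 * Ea/(R T^2),
## to the observed h gives Ea0 = 2/ln2 * R T^2 h ~ 2.88 R T^2 h; the midpoint
## condition k_u(Tmid) = v ln2 Ea/(R Tmid^2) (Laplace approximation of the
## rate integral) then locates Tf.
.kinetic_init <- function(shape, control, rng, v = 1.0) {
  tmi <- shape$tm_initial
  h <- shape$deriv_height
  if (!is.finite(h) || h <= 0) h <- 0.05
  Ea0 <- min(max(2.88 * .Rgas * tmi^2 * h, control$Ea_bounds[1]),
             control$Ea_bounds[2])
  ku_mid <- log(2) * v * Ea0 / (.Rgas * tmi^2)
  Tf0 <- 1 / (1 / tmi + .Rgas * log(ku_mid) / Ea0)
  Tf0 <- min(max(Tf0, rng[1]), rng[2])
  c(Ea = Ea0, Tf = Tf0)
}

#' Experimental fraction-unfolded curve
#'
#' Baseline-corrected, normalized experimental signal
#' `f = (Signal - kN*T - bN) / ((kU - kN)*T + bU - bN)`.  Values are not
#' clamped to `[0, 1]` -- small excursions expose the noise level -- but the
#' result carries attribute `suspect = TRUE` if `|f| > 1.5` anywhere.
#'
#' @param curve A [melting_curve()].
#' @param params Named vector/list with fitted baselines `kN`, `bN`, `kU`,
#'   `bU` (e.g. `coef(fit)`).
#' @return Numeric vector of experimental fractions along the curve.
#' @export
fraction_unfolded <- function(curve, params) {
  stopifnot(inherits(curve, "melting_curve"))
  p <- as.list(params)
  tt <- curve$temperature
  den <- (p$kU - p$kN) * tt + (p$bU - p$bN)
  if (any(den == 0)) stop("baseline separation is zero at some temperature")
  f <- (curve$signal - p$kN * tt - p$bN) / den
  attr(f, "suspect") <- any(abs(f) > 1.5)
  f
}

#' Derivative-peak melting temperature for incomplete curves
#'
#' When a curve lacks a posttransition baseline (unfolding not finished at
#' the end of the scan) the model fit is unreliable; the melting temperature
#' is then estimated from the extremum of the Savitzky-Golay derivative and
#' flagged `no_post_baseline`.  No extrapolated stability measures are
#' computed for such samples.
#'
#' @param curve A [melting_curve()].
#' @param control A [fit_control()].
#' @return List with `Tm` (kelvin or `NA`) and `flags`.
#' @export
fallback_tm <- function(curve, control = fit_control()) {
  deriv <- savgol_derivative(curve, window_k = control$savgol_window_k,
                             polyorder = control$savgol_polyorder)
  centered <- abs(deriv - median(deriv))
  eps <- 1e-8 * (max(abs(curve$signal)) + 1) / diff(range(curve$temperature))
  if (max(centered) <= control$flat_mad_factor * mad(deriv) + eps)
    return(list(Tm = NA_real_, flags = "no_transition"))
  list(Tm = curve$temperature[which.max(centered)], flags = "no_post_baseline")
}

#' Select the readout to analyze from per-readout fits
#'
#' The fluorescence-ratio readout is preferred.  When the ratio fit's
#' BS-factor falls below `bs_threshold` and the F330 fit's BS-factor exceeds
#' it by at least `margin`, F330 is used instead (of the two single
#' wavelengths only F330 is considered; F330 and F350 curves share their
#' shape).
#'
#' @param fits Named list of [fit_unfolding()] results keyed by readout
#'   (e.g. `ratio`, `F330`).
#' @param bs_threshold Ratio BS-factor below which switching is considered
#'   (default 0.25).
#' @param margin Required BS-factor advantage of F330 (default 0.1).
#' @return The selected readout name.
#' @export
select_readout <- function(fits, bs_threshold = 0.25, margin = 0.1) {
  ok <- vapply(fits, function(f) !("fit_failed" %in% f$flags) && !is.null(f$par),
               logical(1))
  if (!any(ok)) stop("fit_failed: no successful fit in any readout")
  bs <- vapply(fits, function(f) if (is.null(f$BS)) -Inf else f$BS, numeric(1))
  bs[!ok] <- -Inf
  if ("ratio" %in% names(fits) && ok[["ratio"]]) {
    if (bs[["ratio"]] >= bs_threshold) return("ratio")
    if ("F330" %in% names(fits) && ok[["F330"]] &&
        bs[["F330"]] >= bs[["ratio"]] + margin) return("F330")
    return("ratio")
  }
  names(which.max(bs))
}

## ---- methods ----

#' @export
print.unfold_fit <- function(x, ...) {
  cat(sprintf("Unfolding fit (%s model) for '%s'\n", x$model, x$curve$sample_id))
  if (is.null(x$par)) {
    cat("  not fitted:", paste(x$flags, collapse = ", "), "\n")
    return(invisible(x))
  }
  core <- if (x$model == "kinetic") c("Ea", "Tf") else c("dHm", "Tm")
  for (nm in core)
    cat(sprintf("  %-4s = %.6g +- %.3g\n", nm, x$par[[nm]], x$sd[[nm]]))
  cat(sprintf("  S = %.4g, BS-factor = %.3f, N = %d\n", x$S, x$BS, x$N))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.unfold_fit <- function(object, ...) object$par

#' @export
vcov.unfold_fit <- function(object, ...) object$cov

#' @export
fitted.unfold_fit <- function(object, ...) {
  predict(object, object$curve$temperature)
}

#' @export
predict.unfold_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$par)) stop("fit did not succeed; no parameters")
  tt <- if (is.null(newdata)) object$curve$temperature
        else if (is.data.frame(newdata)) newdata$temperature
        else as.numeric(newdata)
  if (object$model == "kinetic")
    kinetic_signal(tt, object$par, object$curve$scan_rate)
  else
    equilibrium_signal(tt, object$par, object$dCp)
}

#' @export
residuals.unfold_fit <- function(object, ...) {
  object$curve$signal - fitted(object)
}

#' @export
summary.unfold_fit <- function(object, ...) {
  tab <- if (is.null(object$par)) NULL else
    data.frame(estimate = object$par, sd = object$sd, row.names = names(object$par))
  structure(list(model = object$model, sample_id = object$curve$sample_id,
                 coefficients = tab, S = object$S, BS = object$BS,
                 N = object$N, flags = object$flags,
                 Tonset = object$Tonset, Teucl = object$Teucl),
            class = "summary.unfold_fit")
}

#' @export
print.summary.unfold_fit <- function(x, ...) {
  cat(sprintf("Unfolding fit summary: sample '%s', %s model\n",
              x$sample_id, x$model))
  if (is.null(x$coefficients)) {
    cat("  not fitted:", paste(x$flags, collapse = ", "), "\n")
    return(invisible(x))
  }
  print(signif(as.matrix(x$coefficients), 6))
  cat(sprintf("S (std. error of estimate): %.4g\n", x$S))
  cat(sprintf("BS-factor: %.3f  (0.5-1 excellent; negative unreliable)\n", x$BS))
  if (!is.null(x$Tonset))
    cat(sprintf("Tonset: %.2f K, Teucl: %.2f K\n", x$Tonset, x$Teucl))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.unfold_fit <- function(x, show_baselines = TRUE, ...) {
  cv <- x$curve
  plot(cv$temperature, cv$signal, pch = 16, cex = 0.4, col = "grey40",
       xlab = "Temperature (K)", ylab = sprintf("Signal (%s)", cv$readout),
       main = sprintf("%s (%s)", cv$sample_id, x$model), ...)
  if (!is.null(x$par)) {
    lines(cv$temperature, fitted(x), col = "firebrick", lwd = 2)
    if (show_baselines) {
      abline(x$par[["bN"]], x$par[["kN"]], lty = 3, col = "steelblue")
      abline(x$par[["bU"]], x$par[["kU"]], lty = 3, col = "darkorange")
    }
    tm <- x$par[[if (x$model == "kinetic") "Tf" else "Tm"]]
    abline(v = tm, lty = 2, col = "grey60")
  }
  invisible(x)
}

#' Simulate replicate curves from a fitted model
#'
#' @param object A successful [fit_unfolding()] result.
#' @param nsim Number of replicate curves.
#' @param seed Optional RNG seed.
#' @param noise_sd Gaussian noise SD; defaults to the fit's standard error of
#'   estimate.
#' @param ... Unused.
#' @return List of [melting_curve()] objects.
#' @export
simulate.unfold_fit <- function(object, nsim = 1, seed = NULL,
                                noise_sd = NULL, ...) {
  if (is.null(object$par)) stop("fit did not succeed; nothing to simulate")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- object$S
  model <- if (object$model == "kinetic") "kinetic" else "thermodynamic"
  lapply(seq_len(nsim), function(i)
    simulate_curve(model = model, params = object$par,
                   T_grid = object$curve$temperature, noise_sd = noise_sd,
                   scan_rate = object$curve$scan_rate,
                   sample_id = sprintf("%s_sim%d", object$curve$sample_id, i),
                   readout = object$curve$readout))
}
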