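## Isothermal chemical denaturation by linear extrapolation, and the
## heat-capacity bridge between thermal and chemical unfolding.
##
## The linear extrapolation model (LEM) assumes dG_u(c) = dG0 - m*c in
## denaturant concentration c; the observed signal is the baseline-weighted
## two-state mixture with linear native and unfolded baselines in c
## (six-parameter Santoro-Bolen form).

#' Construct a denaturation series
#'
#' Signal versus denaturant concentration at a fixed temperature.
#'
#' @param conc Concentrations in mol/L, nonnegative and increasing; a zero-
#'   denaturant point is required to anchor the extrapolated free energy.
#' @param signal Signal readings, same length.
#' @param denaturant `"urea"`, `"GuHCl"` or `"other"`.
#' @param temperature Fixed assay temperature, kelvin (default 298.15).
#' @return List of class `denaturation_series`.
#' @export
denaturation_series <- function(conc, signal,
                                denaturant = c("urea", "GuHCl", "other"),
                                temperature = 298.15) {
  denaturant <- match.arg(denaturant)
  conc <- as.numeric(conc); signal <- as.numeric(signal)
  if (length(conc) != length(signal)) stop("conc and signal lengths differ")
  if (any(!is.finite(conc)) || any(!is.finite(signal)))
    stop("conc and signal must be finite")
  if (any(conc < 0)) stop("concentrations must be nonnegative")
  if (any(diff(conc) <= 0)) stop("concentrations must be strictly increasing")
  if (min(conc) > 0)
    stop("a zero-denaturant point is required to anchor dG0")
  stopifnot(temperature > 0)
  structure(list(conc = conc, signal = signal, denaturant = denaturant,
                 temperature = temperature),
            class = "denaturation_series")
}

#' Santoro-Bolen linear-extrapolation signal model
#'
#' `Signal(c) = [(aN + sN*c) + (aU + sU*c) * K] / (1 + K)` with
#' `K = exp((m*c - dG0)/(R*T))`.
#'
#' @param conc Concentrations, mol/L.
#' @param params Named vector/list `aN`, `sN`, `aU`, `sU`, `dG0`, `m`.
#' @param temperature Assay temperature, kelvin.
#' @return Signal values.
#' @export
santoro_bolen_signal <- function(conc, params, temperature = 298.15) {
  p <- as.list(params)
  K <- exp(pmin(pmax((p$m * conc - p$dG0) / (.Rgas * temperature), -700), 700))
  ((p$aN + p$sN * conc) + (p$aU + p$sU * conc) * K) / (1 + K)
}

#' Fit the six-parameter Santoro-Bolen model
#'
#' Bounded Levenberg-Marquardt fit of the linear-extrapolation model to a
#' denaturation series.  Baselines are initialized from straight-line fits
#' to the low- and high-concentration thirds of the series; the m-value from
#' the steepest normalized signal change (`m0 = 4*R*T*h`, `h` the peak
#' |d fraction/dc|) and `dG0 = m0 * c_mid`.
#'
#' @param series A [denaturation_series()] with at least 8 concentrations
#'   spanning the transition.
#' @param max_iter LM iteration cap.
#' @return Object of class `lem_fit` with `par` (named `aN`, `sN`, `aU`,
#'   `sU`, `dG0`, `m`), `sd`, `S`, `cmid` (= dG0/m, mol/L) and the series.
#' @export
fit_santoro_bolen <- function(series, max_iter = 500L) {
  stopifnot(inherits(series, "denaturation_series"))
  cc <- series$conc; yy <- series$signal; temp <- series$temperature
  if (length(cc) < 8) stop("need at least 8 concentrations")
  rng <- range(cc)
  third <- diff(rng) / 3
  lowi <- cc <= rng[1] + third
  highi <- cc >= rng[2] - third
  fN <- lm(yy[lowi] ~ cc[lowi]); fU <- lm(yy[highi] ~ cc[highi])
  aN <- unname(coef(fN)[1]); sN <- unname(coef(fN)[2])
  aU <- unname(coef(fU)[1]); sU <- unname(coef(fU)[2])
  ## steepest normalized change locates the transition
  d <- diff(yy) / diff(cc)
  cmidg <- (cc[-1] + cc[-length(cc)]) / 2
  sep <- abs((aU + sU * cmidg) - (aN + sN * cmidg))
  if (all(sep == 0)) stop("no transition: baselines coincide")
  h <- abs(d) / sep
  i0 <- which.max(h)
  if (!is.finite(h[i0]) || h[i0] <= 0) stop("no transition in range")
  c_mid0 <- cmidg[i0]
  ## flat series guard: steepest change indistinguishable from baseline drift
  if (max(abs(d - median(d))) <= 3 * mad(d) || sd(yy) == 0)
    stop("no transition in range")
  m0 <- 4 * .Rgas * temp * h[i0]
  dG00 <- m0 * c_mid0
  resid <- function(p) {
    names(p) <- c("aN", "sN", "aU", "sU", "dG0", "m")
    santoro_bolen_signal(cc, p, temp) - yy
  }
  init <- c(aN, sN, aU, sU, dG00, m0)
  lower <- c(rep(-Inf, 4), 0, 0)
  upper <- rep(Inf, 6)
  core <- function(p) resid(c(init[1:4], p))
  s1 <- minpack.lm::nls.lm(par = init[5:6], lower = lower[5:6],
                           upper = upper[5:6], fn = core,
                           control = minpack.lm::nls.lm.control(maxiter = max_iter))
  fit <- minpack.lm::nls.lm(par = c(init[1:4], s1$par), lower = lower,
                            upper = upper, fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = max_iter))
  pn <- c("aN", "sN", "aU", "sU", "dG0", "m")
  par <- setNames(as.numeric(fit$par), pn)
  S2 <- fit$deviance / (length(cc) - 6)
  cov <- tryCatch(S2 * chol2inv(chol(fit$hessian)), error = function(e) NULL)
  sdp <- if (is.null(cov)) setNames(rep(NA_real_, 6), pn)
         else setNames(sqrt(pmax(diag(cov), 0)), pn)
  structure(list(par = par, sd = sdp, S = sqrt(S2),
                 cmid = par[["dG0"]] / par[["m"]], series = series,
                 cov = cov),
            class = "lem_fit")
}

#' @export
print.lem_fit <- function(x, ...) {
  cat("Linear-extrapolation (Santoro-Bolen) fit\n")
  cat(sprintf("  dG0 = %.6g +- %.3g J/mol\n", x$par[["dG0"]], x$sd[["dG0"]]))
  cat(sprintf("  m   = %.6g +- %.3g J/mol per mol/L\n", x$par[["m"]], x$sd[["m"]]))
  cat(sprintf("  midpoint c = %.3g mol/L, S = %.4g\n", x$cmid, x$S))
  invisible(x)
}

#' @export
coef.lem_fit <- function(object, ...) object$par

#' @export
predict.lem_fit <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$series$conc
        else if (is.data.frame(newdata)) newdata$conc else as.numeric(newdata)
  santoro_bolen_signal(cc, object$par, object$series$temperature)
}

#' @export
plot.lem_fit <- function(x, ...) {
  s <- x$series
  plot(s$conc, s$signal, pch = 16, xlab = sprintf("[%s] (mol/L)", s$denaturant),
       ylab = "Signal", ...)
  cfine <- seq(min(s$conc), max(s$conc), length.out = 200)
  lines(cfine, predict(x, cfine), col = "firebrick", lwd = 2)
  abline(v = x$cmid, lty = 2, col = "grey60")
  invisible(x)
}

#' Heat-capacity change from the enthalpy-temperature dependence
#'
#' By Kirchhoff's relation the slope of the melting enthalpy versus melting
#' temperature (obtained, e.g., from thermal unfolding at increasing
#' denaturant concentrations) equals the heat-capacity change of unfolding.
#' Ordinary least squares; the slope SD comes from the regression.
#'
#' @param Tm Melting temperatures, kelvin (at least 3, spanning >= 2 K).
#' @param dHm Matching melting enthalpies, J/mol.
#' @return Named vector `c(dCp = slope, sd = slope SD)` in J/mol/K.
#' @export
dcp_from_dhm_tm <- function(Tm, dHm) {
  if (length(Tm) != length(dHm)) stop("Tm and dHm lengths differ")
  if (length(Tm) < 3) stop("need at least 3 (Tm, dHm) points")
  if (diff(range(Tm)) < 2) stop("insufficient Tm range (< 2 K)")
  fit <- lm(dHm ~ Tm)
  sm <- summary(fit)$coefficients
  c(dCp = unname(coef(fit)[2]), sd = unname(sm["Tm", "Std. Error"]))
}

#' Reconcile thermal and chemical estimates of the unfolding free energy
#'
#' Thermal unfolding extrapolated to the reference temperature with the
#' heat-capacity term neglected overestimates dG; adding the neglected term
#' (always negative for `Tref < Tm`) should bring the thermal estimate in
#' line with the chemical-denaturation value at the same temperature.
#'
#' @param dG_thermal Zero-dCp thermal estimate of dG at `tref`, J/mol.
#' @param Tm Melting temperature of the thermal fit, kelvin.
#' @param chem A [fit_santoro_bolen()] result (or a number: chemical dG0).
#' @param dCp Heat-capacity change, J/mol/K (e.g. from [dcp_from_dhm_tm()]).
#' @param tref Reference temperature, kelvin.
#' @return Data frame with the uncorrected and corrected thermal estimates,
#'   the chemical estimate, the applied correction and both differences.
#' @export
reconcile_thermal_chemical <- function(dG_thermal, Tm, chem, dCp,
                                       tref = .Tref_std) {
  dG_chem <- if (inherits(chem, "lem_fit")) chem$par[["dG0"]] else as.numeric(chem)
  corr <- if (dCp == 0) 0 else dcp_neglect_error(dCp, tref, Tm)
  corrected <- dG_thermal + corr
  data.frame(dG_thermal_uncorrected = dG_thermal,
             dG_thermal_corrected = corrected,
             dG_chemical = dG_chem,
             dcp_correction = corr,
             diff_uncorrected = dG_thermal - dG_chem,
             diff_corrected = corrected - dG_chem)
}
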