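## Forward models of sigmoidal unfolding curves and their derived quantities.
##
## Three parameterizations of the same observable shape:
##   * equilibrium two-state: Gibbs-Helmholtz dG_u(T), van't Hoff K_u,
##     fraction unfolded f = K/(1+K);
##   * irreversible kinetic: Arrhenius-type rate k_u(T), native fraction x_N
##     from a first-order ODE in temperature at scan rate v;
##   * empirical: melting temperature plus onset temperature.
## All temperatures kelvin, energies J/mol, R = 8.314 J/mol/K.

#' Gibbs free energy of unfolding at temperature T
#'
#' Gibbs-Helmholtz form
#' `dG_u(T) = dHm * (1 - T/Tm) + dCp * (T - Tm - T * log(T/Tm))`.
#' With `dCp = 0` this is the pure van't Hoff two-state model.
#'
#' @param T Temperature(s), kelvin.
#' @param dHm Van't Hoff enthalpy of unfolding at `Tm`, J/mol.
#' @param Tm Melting temperature, kelvin.
#' @param dCp Heat-capacity change of unfolding, J/mol/K (default 0; fixed,
#'   never fitted).
#' @return dG_u in J/mol; exactly 0 at `T = Tm`.
#' @export
gibbs_free_energy <- function(T, dHm, Tm, dCp = 0) {
  stopifnot(all(T > 0), Tm > 0)
  dHm * (1 - T / Tm) + dCp * (T - Tm - T * log(T / Tm))
}

## equilibrium fraction unfolded; exponent clamped to +-700 for overflow safety
.f_unfolded <- function(T, dHm, Tm, dCp = 0) {
  dG <- gibbs_free_energy(T, dHm, Tm, dCp)
  K <- exp(pmin(pmax(-dG / (.Rgas * T), -700), 700))
  K / (1 + K)
}

#' Equilibrium two-state signal model
#'
#' Baseline-weighted mixture of native and unfolded state signals:
#' `Signal(T) = (kN*T + bN) * (1 - f) + (kU*T + bU) * f` with
#' `f = K/(1+K)`, `K = exp(-dG_u(T) / (R*T))`.
#'
#' @param T Temperature(s), kelvin.
#' @param params Named vector/list with `kN`, `bN`, `kU`, `bU`, `dHm`, `Tm`.
#' @param dCp Heat-capacity change, J/mol/K (fixed; default 0).
#' @return Signal in the curve's units.
#' @export
equilibrium_signal <- function(T, params, dCp = 0) {
  p <- as.list(params)
  f <- .f_unfolded(T, p$dHm, p$Tm, dCp)
  (p$kN * T + p$bN) * (1 - f) + (p$kU * T + p$bU) * f
}

#' Unfolding rate constant of the kinetic model
#'
#' `k_u(T) = exp(-Ea/R * (1/T - 1/Tf))`; `Tf` is the temperature where the
#' rate constant equals 1 (per minute).
#'
#' @param T Temperature(s), kelvin.
#' @param Ea Activation energy, J/mol.
#' @param Tf Temperature of unit rate constant, kelvin.
#' @return Rate constant, 1/min.
#' @export
kinetic_rate <- function(T, Ea, Tf) {
  exp(pmin(pmax(-Ea / .Rgas * (1 / T - 1 / Tf), -700), 700))
}

## Cumulative integral of the Arrhenius-type rate along the scan.
## Because log k_u is smooth and nearly linear in T, each (sub)interval is
## integrated with the rule that is exact for exponential integrands
## (the log-mean of the endpoint rates times the width); the grid is refined
## 8-fold internally, which keeps the quadrature error of x_N below ~1e-6
## even on coarse 0.5 K instrument grids and very steep transitions.
.kinetic_integral <- function(T_grid, Ea, Tf, refine = 8L) {
  n <- length(T_grid)
  step <- rep(diff(T_grid) / refine, each = refine)
  t_fine <- c(rep(T_grid[-n], each = refine) +
                step * rep(seq_len(refine) - 1L, n - 1L),
              T_grid[n])
  lk <- -Ea / .Rgas * (1 / t_fine - 1 / Tf)
  lk <- pmin(lk, 700)
  k <- exp(lk)
  dT <- diff(t_fine)
  dl <- diff(lk)
  kl <- k[-length(k)]; kr <- k[-1]
  seg <- ifelse(abs(dl) < 1e-12, (kl + kr) / 2 * dT, (kr - kl) / dl * dT)
  I_fine <- c(0, cumsum(seg))
  I_fine[seq(1L, length(t_fine), by = refine)]
}

#' Native fraction of the irreversible kinetic model
#'
#' Solves `dx_N/dT = -(1/v) * k_u(T) * x_N`, `x_N(T_min) = 1`, in closed form
#' `x_N(T) = exp(-(1/v) * integral(k_u))` with cumulative quadrature of the
#' rate along the grid (piecewise exact-exponential rule on an internally
#' refined grid).  The result starts at exactly 1, is nonincreasing and
#' stays in `[0, 1]`.
#'
#' @param T_grid Increasing temperature grid, kelvin; the first element is
#'   the start of the scan.
#' @param Ea Activation energy, J/mol.
#' @param Tf Temperature of unit rate constant, kelvin.
#' @param v Scan rate, K/min (default 1).
#' @return Vector of native fractions along `T_grid`.
#' @export
kinetic_xn <- function(T_grid, Ea, Tf, v = 1.0) {
  if (any(diff(T_grid) <= 0)) stop("nonmonotonic temperature grid")
  stopifnot(v > 0, Ea > 0)
  exp(-.kinetic_integral(T_grid, Ea, Tf) / v)
}

#' Kinetic signal model
#'
#' Baseline mixture applied to the native fraction, mirroring the equilibrium
#' signal model: `Signal = (kN*T + bN) * x_N + (kU*T + bU) * (1 - x_N)`.
#'
#' @param T_grid Increasing temperature grid, kelvin.
#' @param params Named vector/list with `kN`, `bN`, `kU`, `bU`, `Ea`, `Tf`.
#' @param v Scan rate, K/min.
#' @return Signal along the grid.
#' @export
kinetic_signal <- function(T_grid, params, v = 1.0) {
  p <- as.list(params)
  xn <- kinetic_xn(T_grid, p$Ea, p$Tf, v)
  (p$kN * T_grid + p$bN) * xn + (p$kU * T_grid + p$bU) * (1 - xn)
}

#' Kinetic stability measure pk_u at standard temperature
#'
#' Negative decadic logarithm of the unfolding rate constant extrapolated to
#' 298.15 K: `pku = -log10 k_u(298.15)`.  Higher values mean slower unfolding
#' at ambient temperature, i.e. a more stable sample.  Zero when
#' `Tf = 298.15` (unit rate constant by definition of `Tf`).
#'
#' @param Ea Activation energy, J/mol.
#' @param Tf Temperature of unit rate constant, kelvin.
#' @return Dimensionless pk_u at 298.15 K.
#' @export
pku_std <- function(Ea, Tf) {
  (Ea / .Rgas) * (1 / .Tref_std - 1 / Tf) / log(10)
}

#' Onset temperature of unfolding
#'
#' Temperature at which the fitted equilibrium model reaches a given fraction
#' unfolded (default 1%), i.e. the root of
#' `dG_u(T)/(R*T) = log((1-q)/q)` on `[t_scan_min, Tm]`, located by bracketed
#' root search to 1e-4 K.  If the onset lies below the start of the scan the
#' scan start is returned with attribute `extrapolated = TRUE`.
#'
#' @param dHm,Tm,dCp Equilibrium model parameters (J/mol, K, J/mol/K).
#' @param onset_fraction Fraction unfolded defining the onset (default 0.01;
#'   must be in (0, 0.5]).
#' @param t_scan_min Lower end of the experimental scan, kelvin.
#' @return Onset temperature (kelvin) with logical attribute `extrapolated`.
#' @export
t_onset <- function(dHm, Tm, dCp = 0, onset_fraction = 0.01,
                    t_scan_min = 293.15) {
  stopifnot(onset_fraction > 0, onset_fraction <= 0.5, t_scan_min < Tm)
  if (onset_fraction == 0.5) return(structure(Tm, extrapolated = FALSE))
  g <- function(T) .f_unfolded(T, dHm, Tm, dCp) - onset_fraction
  if (g(t_scan_min) >= 0)
    return(structure(t_scan_min, extrapolated = TRUE))
  root <- uniroot(g, c(t_scan_min, Tm), tol = 1e-4)$root
  structure(root, extrapolated = FALSE)
}

#' Euclidean stability measure from melting and onset temperatures
#'
#' Distance of the point `(Tm, Tonset)` from the origin of the
#' temperature-temperature plane: `sqrt(Tm^2 + Tonset^2)`.  Rewards samples
#' with a good combination of late midpoint and late onset.
#'
#' @param Tm Melting temperature, kelvin.
#' @param Tonset Onset temperature, kelvin.
#' @return T_eucl in kelvin.
#' @export
t_eucl <- function(Tm, Tonset) {
  stopifnot(all(Tm > 0), all(Tonset > 0))
  sqrt(Tm^2 + Tonset^2)
}

#' Systematic error of neglecting dCp in dG extrapolation
#'
#' The term dropped from the Gibbs-Helmholtz expression when the
#' heat-capacity change is assumed zero:
#' `Error(Tref, Tm) = dCp * (Tref - Tm - Tref * log(Tref/Tm))`.
#' For `Tref < Tm` this is always negative, so zero-dCp extrapolation
#' overestimates the free energy of unfolding.
#'
#' @param dCp Heat-capacity change, J/mol/K.
#' @param Tref Reference temperature, kelvin (must be below `Tm`).
#' @param Tm Melting temperature, kelvin.
#' @return Error in J/mol (<= 0 for nonnegative dCp).
#' @export
dcp_neglect_error <- function(dCp, Tref, Tm) {
  stopifnot(Tref > 0)
  if (any(Tref >= Tm)) stop("Tref must be below Tm")
  dCp * (Tref - Tm - Tref * log(Tref / Tm))
}
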