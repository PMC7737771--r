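---
title: "Models and methods for thermal-unfolding curve analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for thermal-unfolding curve analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltcurve)
```

# Scope and data model

`meltcurve` analyzes bulk signal-versus-temperature measurements of protein
unfolding — intrinsic tryptophan fluorescence (F330, F350 or their ratio),
circular dichroism, or any readout that traces a sigmoidal transition — and
isothermal chemical denaturation series.  All temperatures are kelvin
internally; degrees Celsius exist only at the input boundary and only when
requested explicitly.  A curve is at least 20 retained points with strictly
increasing temperatures; every preprocessing step is appended to the
curve's history, so a processed curve documents how it was produced.

A bulk measurement reports an apparent "melting unit": whatever molecular
ensemble produces the optical signal.  All fitted quantities are apparent
properties of that unit, which is the correct level of description for
ranking screen conditions, not for single-molecule mechanism.

# The three models

**Equilibrium two-state.**  The free energy of unfolding follows the
Gibbs–Helmholtz relation
$$\Delta G_u(T) = \Delta H_m\left(1 - \frac{T}{T_m}\right)
  + \Delta C_p\left(T - T_m - T\ln\frac{T}{T_m}\right),$$
with the signal modeled as the baseline-weighted mixture
$S(T) = (k_N T + b_N)(1-f) + (k_U T + b_U)f$,
$f = K/(1+K)$, $K = \exp(-\Delta G_u/RT)$, $R = 8.314$ J/mol/K.
$\Delta C_p$ is held fixed (default 0) rather than fitted: a thermal scan
alone does not constrain it, and in screening mode one compares conditions,
where the zero-$\Delta C_p$ bias largely cancels for melting-temperature
differences within roughly 10–15 K.  The systematic error of neglecting it,
$\Delta C_p (T_{ref} - T_m - T_{ref}\ln(T_{ref}/T_m))$, is available as
`dcp_neglect_error()` and is always negative below $T_m$ — zero-$\Delta C_p$
extrapolation overestimates stability.

**Irreversible kinetic.**  Many proteins, especially large complexes and
membrane proteins, unfold irreversibly; equilibrium thermodynamics then
reads a scan-rate-dependent artifact as a free energy.  The kinetic model
treats unfolding as a first-order decay of the native fraction along the
scan, $dx_N/dT = -(1/v)\,k_u(T)\,x_N$ with
$k_u(T) = \exp(-E_a/R\,(1/T - 1/T_f))$, $x_N = 1$ at the scan start, $v$
the scan rate in K/min.  $T_f$ (the temperature of unit rate constant)
positions the curve; $E_a$ sets its steepness.

**Empirical.**  Two characteristic temperatures describe the transition
without thermodynamic commitment: the midpoint $T_m$ and the onset
$T_{onset}$.  "First detectable deviation from the baseline" is
noise-dependent, so the onset is defined on the *fitted* curve as the
temperature of 1% unfolded (configurable `onset_fraction`), found by
bracketed bisection to $10^{-4}$ K; onsets below the scan start return the
scan start with an `onset_extrapolated` flag.

**Ranking measures.**  Each model collapses to one number per sample:
$\Delta G_u^{\circ\prime}$ at 298.15 K and 100 kPa; $pk_u^{\circ\prime} =
-\log_{10} k_u(298.15\,\mathrm{K})$ (decadic, by pK convention — the
defining property $pk_u = 0$ at $T_f = 298.15$ K holds in any base, and
base 10 matches how biochemists read pK scales); and
$T_{eucl} = \sqrt{T_m^2 + T_{onset}^2}$, the distance of $(T_m, T_{onset})$
from the origin of the temperature plane.  All three reward both a late
midpoint and a steep transition.

# Numerical methods

**Kinetic forward solve.**  The kinetic ODE is linear, so
$x_N(T) = \exp(-(1/v)\int_{T_{min}}^{T} k_u)$ exactly; only the rate
integral needs quadrature.  Because $\ln k_u$ is smooth and nearly linear
in $T$, each interval is integrated with the rule that is exact for
exponential integrands (interval width times the log-mean of the endpoint
rates), on a grid refined 8-fold internally — the rate function is analytic,
so refinement costs only function evaluations.  Measured worst-case error
of $x_N$ against a dense reference is $1.3\times10^{-7}$ on 0.1 K grids and
$3\times10^{-6}$ on 0.5 K instrument grids, across activation energies up
to 4 MJ/mol.  Plain trapezoid quadrature on the data grid errs by up to
$5\times10^{-4}$ on the same cases and was rejected.  The test suite checks
the closed form against an independent fourth-order Runge–Kutta solve of
the log-state equation $d\ln x_N/dT = -k_u/v$ (the transformation avoids
the stiffness of the raw equation past the transition, where explicit
solvers overflow).

**Initialization.**  Good start values, not clever optimizers, decide
whether sigmoid fits converge.  Baselines come from straight-line fits to
the first and last 10 K of the scan; comparing the two lines at the scan
midpoint classifies the curve as S-shaped (rising) or Z-shaped (falling).
The initial $T_m$ is the global extremum (maximum for S, minimum for Z) of
the Savitzky–Golay first derivative (order 4, 10 K window; windows stated
in kelvin are converted to odd point counts via the median step), restricted
to the region between the baseline stretches, ties broken toward lower
temperature.  The enthalpy always starts at 100,000 J/mol — a deliberately
generic value of the right order for typical melting units.  For the
kinetic model no comparable convention exists, so the start values are
derived from the derivative peak height $h$ (peak $|df/dT|$): matching the
midpoint slope of the two families gives $E_a^{(0)} = (2/\ln 2) R T_{1/2}^2
h \approx 2.88\,R T_{1/2}^2 h$, and the Laplace approximation of the rate
integral at the midpoint, $k_u(T_{1/2}) \approx v \ln 2\, E_a/(R T_{1/2}^2)$,
then locates $T_f^{(0)}$.

**Optimization.**  Bounded Levenberg–Marquardt (minpack) in two stages:
stage one refines only the core pair ($\Delta H_m, T_m$ or $E_a, T_f$) with
baselines frozen at their stretch estimates; stage two releases all six
parameters.  The staged start matters: from the generic enthalpy start, a
one-shot six-parameter fit of steep transitions can stall on a plateau with
the midpoint pinned at a bound (observed in 3 of 25 random steep/shallow
cases), while the staged fit recovered 25 of 25.  Bounds: midpoint within
the scan range, $\Delta H_m \in [60, 4000]$ kJ/mol,
$E_a \in [10, 4000]$ kJ/mol, baselines unbounded.  Fitting is fully
deterministic — identical inputs and configuration reproduce identical
tables.

**Uncertainties and quality.**  Parameter SDs are square roots of the
diagonal of $S^2 (J^\top J)^{-1}$ with
$S = \sqrt{\sum(F_{exp}-F_{fit})^2/(N-n)}$; a singular Jacobian marks the
fit failed rather than inventing a pseudo-inverse.  Fit quality is the
baseline-separation factor $BS = 1 - 6S/|k_U T_m + b_U - k_N T_m - b_N|$;
the absolute value makes Z-curves score like S-curves (the defining
formula is written for rising curves).  Fits with $SD(T_m) > 0.5$ K are
flagged `unreliable_tm_sd` but kept in the table — the caller filters, so
screens remain auditable.  Flat curves (derivative extremum within 3
derivative-MADs of the bulk level, with a floating-point floor) are flagged
`no_transition` and never fitted.  Curves lacking a posttransition baseline
(unfolding unfinished at the scan end) route to `fallback_tm()`: the
derivative-peak temperature with flag `no_post_baseline`, and no
extrapolated measures are reported for them.

**Degenerate inputs.**  Nonmonotonic temperature vectors are rejected at
I/O; interior missing points are dropped, never interpolated, with the
count recorded; coincident baselines give $BS = -\infty$ and
`no_transition`; onset extrapolation and readout switching
(`select_readout()`: prefer the fluorescence ratio unless its BS-factor is
below 0.25 *and* F330 beats it by at least 0.1) are flagged explicitly.

# Chemical denaturation and the heat-capacity bridge

Isothermal denaturant series are fit to the six-parameter Santoro–Bolen
form $S(c) = [(a_N + s_N c) + (a_U + s_U c)K]/(1+K)$,
$K = \exp((mc - \Delta G^{\circ\prime})/RT)$, with linear baselines in
concentration on both sides (the baseline order is a modeling choice; linear
is the standard default and matches the thermal-side convention).
Initialization mirrors the thermal fit: end-stretch lines, steepest
normalized change for the midpoint, $m^{(0)} = 4RTh$.  The heat-capacity
change comes from Kirchhoff's relation — the ordinary-least-squares slope
of $\Delta H_m$ versus $T_m$ across a denaturant series of thermal fits —
and `reconcile_thermal_chemical()` reports the zero-$\Delta C_p$ thermal
estimate, the $\Delta C_p$-corrected one (adding the neglected term), the
chemical value, and their differences.  On synthetic truth the corrected
difference closes to within fit uncertainty while the uncorrected one keeps
the full neglect bias (several kJ/mol for a typical single domain).

# The synthetic generator: what it emulates and what it does not

`simulate_curve()` forward-evaluates either model and adds homoscedastic
Gaussian noise (a heteroscedastic mechanism is not modeled; instrument
noise at the 1% level is close to flat across a scan).  Defaults emulate a
capillary fluorescence-ratio experiment: 293.15–368.15 K in 0.5 K steps at
1 K/min, pretransition ratio ≈ 0.8 and posttransition ≈ 0.95 with small
positive slopes, noise stated as a fraction (default 1%) of the transition
height — the typical quality of modern intrinsic-fluorescence data.

`simulate_panel()` generates screens.  Its default `"kirchhoff"` family
draws $T_m$ uniformly over the requested range and places $\Delta H_m$ on
the straight line through the range ends with 5% multiplicative scatter —
the middle of the 3–10% replicate-level relative error typical for enthalpy
estimates.  This coupling is the defining covariance structure of a real
single-protein screen: one melting unit measured across conditions moves
along its heat-capacity line, which is exactly what the $\Delta H_m(T_m)$
regression in the chemical-denaturation workflow measures.  An
`"independent"` family (uncoupled uniform draws) exists for
parameter-recovery sweeps; it does not represent any physical screen, since
it implies a different protein in every well.

What passing tests on these panels demonstrate: correct model algebra,
quadrature, optimizer convergence, uncertainty calibration
($3\sigma$ coverage, $1/\sqrt{N}$ scaling) and the reliability filter.
What they cannot demonstrate: robustness to aggregation scattering,
photobleaching drift, evaporation, multi-transition curves, or baseline
curvature — real-data pathologies outside the two-state/irreversible model
families.  The preprocessing "rescue" steps (trim, median filter, binning)
exist for exactly those cases and are validated only on their defined
point-level behavior.

# Validation conditions and known limitations

The concordance study (also recomputed by `scripts/acceptance.R`) uses a
40-curve Kirchhoff panel spanning $T_m$ 300–360 K and $\Delta H_m$
100–1,000 kJ/mol at 1% noise, sizes chosen to exercise the full bound box
in seconds on one core; fits that fail the 0.5 K rule are discarded before
correlating, matching the screening workflow.  On such panels the minimum
pairwise Kendall $\tau$ among the three measures is 0.92–0.98 across seeds,
and the minimum pairwise Pearson $r$ is 0.975–0.986.

The Pearson floor is structural, not a fitting defect: over a tenfold
enthalpy span $\Delta G_u^{\circ\prime}$ is strongly convex in $T_m$ while
$T_{eucl}$ is nearly linear in it, and the Pearson correlation between a
convex and a linear function of the same latent variable is bounded below 1
(about 0.966 for this span even for noise-free, perfectly coupled panels).
Reported correlations above 0.99 arise on real screens whose stability
range is far narrower than this deliberately wide synthetic box; rank-order
agreement, which is what hit-picking uses, is unaffected by the convexity.

Other limitations, by design: no multi-transition (two-sigmoid) fitting;
no global multi-curve fits; $\Delta C_p$ never free in thermal fits; no
spline baselines; vendor spreadsheet dialects are left to adapters — the
canonical input is the documented wide CSV (`temperature,<id1>,<id2>,...`),
with xlsx reading available when readxl is installed and CSV as the export
format.
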