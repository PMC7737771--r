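chem_params <- c(aN = 0.85, sN = 0.003, aU = 1.05, sU = 0.006,
                 dG0 = 2e4, m = 5e3)

fixture_series <- function(noise_sd = 0, seed = NULL, conc = seq(0, 8, 0.5)) {
  if (!is.null(seed)) set.seed(seed)
  y <- santoro_bolen_signal(conc, chem_params)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  denaturation_series(conc, y)
}

## same protein-like baselines with a caller-chosen dG0; wider concentration
## range so the transition stays bracketed for large dG0
fixture_series2 <- function(dG0, conc = seq(0, 12, 0.5)) {
  p <- chem_params
  p[["dG0"]] <- dG0
  denaturation_series(conc, santoro_bolen_signal(conc, p))
}

test_that("series construction enforces the concentration grammar", {
  expect_error(denaturation_series(c(1, 2, 3) * 1.0, c(1, 2, 3) * 1.0,
                                   temperature = 298.15),
               "zero-denaturant")
  expect_error(denaturation_series(c(0, 2, 1), c(1, 2, 3)), "increasing")
  expect_error(denaturation_series(c(0, -1, 2), c(1, 2, 3)), "nonnegative")
})

test_that("the linear-extrapolation fit recovers noiseless truth to 0.1%", {
  fit <- fit_santoro_bolen(fixture_series())
  expect_lt(abs(coef(fit)[["dG0"]] - 2e4) / 2e4, 1e-3)
  expect_lt(abs(coef(fit)[["m"]] - 5e3) / 5e3, 1e-3)
  ## at the midpoint concentration dG0/m the protein is half unfolded:
  ## the fitted signal is the average of the two baselines there
  cmid <- fit$cmid
  pl <- as.list(coef(fit))
  mid <- ((pl$aN + pl$sN * cmid) + (pl$aU + pl$sU * cmid)) / 2
  expect_equal(predict(fit, cmid), mid, tolerance = 1e-9)
  expect_equal(cmid, 4, tolerance = 1e-3)
})

test_that("degenerate denaturation series are rejected", {
  flat <- denaturation_series(seq(0, 8, 0.5), rep(1, 17))
  expect_error(fit_santoro_bolen(flat), "no transition")
  expect_error(fit_santoro_bolen(fixture_series(conc = seq(0, 8, 2))),
               "at least 8")
})

test_that("the heat-capacity change is the dHm-vs-Tm slope", {
  Tm <- c(318, 322, 326, 330, 334)
  dHm <- 4846 * Tm - 1.2e6
  ## exact line: lm warns that the fit is perfect, which is the point here
  est <- suppressWarnings(dcp_from_dhm_tm(Tm, dHm))
  expect_equal(est[["dCp"]], 4846, tolerance = 1e-9)
  expect_error(dcp_from_dhm_tm(Tm[1:2], dHm[1:2]), "at least 3")
  expect_error(dcp_from_dhm_tm(c(330, 330.5, 331), dHm[1:3]),
               "insufficient Tm range")
  ## with 2% noise on dHm the slope stays within 3 reported SDs
  set.seed(61)
  Tm10 <- seq(315, 335, length.out = 10)
  ok <- 0
  for (r in 1:10) {
    dH <- (4846 * Tm10 - 1.2e6) * (1 + rnorm(10, 0, 0.02))
    est <- dcp_from_dhm_tm(Tm10, dH)
    if (abs(est[["dCp"]] - 4846) <= 3 * est[["sd"]]) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("dCp correction reconciles thermal and chemical free energies", {
  ## identities first
  rep0 <- reconcile_thermal_chemical(40000, 330, 35000, dCp = 0)
  expect_equal(rep0$dG_thermal_corrected, rep0$dG_thermal_uncorrected)
  rep1 <- reconcile_thermal_chemical(40000, 330, 35000, dCp = 5000)
  expect_equal(rep1$dG_thermal_uncorrected - rep1$dG_thermal_corrected,
               -dcp_neglect_error(5000, 298.15, 330))

  ## end-to-end synthetic loop: one protein, denaturant shifts the melting
  ## temperature; enthalpy follows the Kirchhoff line with dCp = 5000
  dCp_true <- 5000
  Tm0 <- 330; dHm0 <- 4.5e5
  Tms <- c(330, 326, 322, 318, 314)
  fits <- lapply(Tms, function(Tm) {
    dHm <- dHm0 + dCp_true * (Tm - Tm0)
    cv <- simulate_curve("thermodynamic",
                         c(default_baselines(), dHm = dHm, Tm = Tm),
                         dCp = dCp_true)
    fit_unfolding(cv)   # screening-mode fit: dCp assumed zero
  })
  Tm_hat <- vapply(fits, function(f) coef(f)[["Tm"]], numeric(1))
  dHm_hat <- vapply(fits, function(f) coef(f)[["dHm"]], numeric(1))
  dcp_est <- dcp_from_dhm_tm(Tm_hat, dHm_hat)
  expect_equal(dcp_est[["dCp"]], dCp_true, tolerance = 0.15)

  ## chemical side knows the true (dCp-aware) free energy at 298.15 K
  dG_true <- gibbs_free_energy(298.15, dHm0, Tm0, dCp_true)
  chem <- fit_santoro_bolen(fixture_series2(dG_true))
  thermal_dG <- gibbs_free_energy(298.15, dHm_hat[1], Tm_hat[1])
  rep2 <- reconcile_thermal_chemical(thermal_dG, Tm_hat[1], chem,
                                     dCp = dcp_est[["dCp"]])
  expect_lt(abs(rep2$diff_corrected), abs(rep2$diff_uncorrected))
  expect_lt(abs(rep2$diff_corrected), 2000)   # J/mol, ~5% of dG
})
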