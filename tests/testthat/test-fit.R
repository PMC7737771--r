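test_that("noiseless curves of both families are recovered essentially exactly", {
  set.seed(41)
  for (i in 1:8) {
    dHm <- runif(1, 1.5e5, 9e5); Tm <- runif(1, 305, 355)
    fit <- fit_unfolding(fixture_thermo_curve(dHm = dHm, Tm = Tm))
    expect_lt(abs(coef(fit)[["Tm"]] - Tm), 0.01)
    expect_lt(abs(coef(fit)[["dHm"]] - dHm) / dHm, 1e-3)
    expect_equal(fit$BS, 1, tolerance = 1e-3)   # S ~ 0 for a perfect fit
  }
  for (i in 1:8) {
    Ea <- runif(1, 1.5e5, 9e5); Tf <- runif(1, 310, 350)
    fit <- fit_unfolding(fixture_kinetic_curve(Ea = Ea, Tf = Tf), "kinetic")
    expect_lt(abs(coef(fit)[["Tf"]] - Tf), 0.01)
    expect_lt(abs(coef(fit)[["Ea"]] - Ea) / Ea, 1e-3)
  }
})

test_that("reported uncertainties cover the truth under noise", {
  hits <- 0
  for (s in 1:20) {
    cv <- fixture_thermo_curve(dHm = 4e5, Tm = 330,
                               noise_sd = 0.01 * fixture_height(), seed = s)
    fit <- fit_unfolding(cv)
    if (abs(coef(fit)[["Tm"]] - 330) <= 3 * fit$sd[["Tm"]]) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("flat curves are flagged, not fitted", {
  temps <- std_grid()
  flat <- melting_curve(temps, 0.0003 * temps + 0.8)
  fit <- fit_unfolding(flat)
  expect_true("no_transition" %in% fit$flags)
  expect_null(fit$par)
  expect_output(print(fit), "not fitted")
})

test_that("the baseline-separation factor follows its algebra", {
  b <- default_baselines()
  sep_at <- function(Tm) abs((b[["kU"]] - b[["kN"]]) * Tm +
                             (b[["bU"]] - b[["bN"]]))
  Tm <- 330
  expect_equal(bs_factor(0, b[["kN"]], b[["bN"]], b[["kU"]], b[["bU"]], Tm), 1)
  expect_equal(bs_factor(sep_at(Tm) / 6, b[["kN"]], b[["bN"]], b[["kU"]],
                         b[["bU"]], Tm), 0)
  ## separation 0.06 with S = 0.005: 1 - 0.03/0.06
  expect_equal(bs_factor(0.005, 0, 0, 0, 0.06, Tm), 0.5)
  ## Z-curves score like S-curves of the same magnitude
  expect_equal(bs_factor(0.005, 0, 0.06, 0, 0, Tm), 0.5)
  ## coincident baselines cannot separate a transition
  expect_equal(bs_factor(0.005, 0, 0.3, 0, 0.3, Tm), -Inf)
})

test_that("experimental fraction unfolded inverts the signal model", {
  p <- c(default_baselines(), dHm = 4e5, Tm = 330)
  pl <- as.list(p)
  temps <- std_grid()
  ## a signal lying on the native baseline is 0% unfolded
  on_base <- melting_curve(temps, pl$kN * temps + pl$bN)
  expect_lt(max(abs(fraction_unfolded(on_base, p))), 1e-12)
  ## parallel coincident baselines make normalization impossible
  expect_error(fraction_unfolded(on_base, c(kN = 0, bN = 1, kU = 0, bU = 1)),
               "zero")
})

test_that("incomplete curves fall back to the derivative-peak Tm", {
  cut <- simulate_curve("thermodynamic",
                        c(default_baselines(), dHm = 4e5, Tm = 350),
                        truncate_at = 0.6)
  expect_lt(max(cut$temperature), 368.15)
  fb <- fallback_tm(cut)
  expect_equal(fb$flags, "no_post_baseline")
  expect_equal(fb$Tm, 350, tolerance = 1 / 350)

  flat <- melting_curve(std_grid(), rep(1, 151))
  expect_equal(fallback_tm(flat)$flags, "no_transition")
})

test_that("readout selection prefers the ratio unless it is clearly worse", {
  mkfit <- function(bs) structure(list(BS = bs, flags = character(0),
                                       par = c(Tm = 330)),
                                  class = "unfold_fit")
  expect_equal(select_readout(list(ratio = mkfit(0.8), F330 = mkfit(0.9))),
               "ratio")
  expect_equal(select_readout(list(ratio = mkfit(0.1), F330 = mkfit(0.7))),
               "F330")
  ## margin not met: stay with the ratio
  expect_equal(select_readout(list(ratio = mkfit(0.2), F330 = mkfit(0.22))),
               "ratio")
  failed <- structure(list(BS = NA_real_, flags = "fit_failed", par = NULL),
                      class = "unfold_fit")
  expect_error(select_readout(list(ratio = failed)), "fit_failed")
})

test_that("the reported SD(Tm) shrinks like one over sqrt(N)", {
  sd_at_step <- function(step) {
    grid <- seq(293.15, 368.15, by = step)
    sds <- vapply(1:6, function(s) {
      cv <- simulate_curve("thermodynamic",
                           c(default_baselines(), dHm = 4e5, Tm = 330),
                           T_grid = grid, noise_sd = 0.01 * fixture_height(),
                           seed = 100 + s)
      fit_unfolding(cv)$sd[["Tm"]]
    }, numeric(1))
    mean(sds)
  }
  ratio <- sd_at_step(0.5) / sd_at_step(0.125)   # 4x the points
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("fit objects expose the standard modelling interface", {
  cv <- fixture_thermo_curve(noise_sd = 0.0015, seed = 5)
  fit <- fit_unfolding(cv, "empirical")
  expect_named(coef(fit), c("kN", "bN", "kU", "bU", "dHm", "Tm"))
  expect_equal(dim(vcov(fit)), c(6L, 6L))
  expect_equal(fitted(fit) + residuals(fit), cv$signal)
  expect_equal(predict(fit, 330),
               equilibrium_signal(330, coef(fit)), tolerance = 1e-12)
  expect_output(print(summary(fit)), "BS-factor")
  ## the empirical description rides on the thermodynamic fit
  fit_th <- fit_unfolding(cv, "thermodynamic")
  expect_identical(coef(fit)[["Tm"]], coef(fit_th)[["Tm"]])
  expect_lt(fit$Tonset, coef(fit)[["Tm"]])
  ## simulate() is reproducible
  s1 <- simulate(fit, nsim = 2, seed = 7)
  s2 <- simulate(fit, nsim = 2, seed = 7)
  expect_identical(s1[[2]]$signal, s2[[2]]$signal)
})
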