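## Frozen expected values below were computed by independent arithmetic on
## the defining formulas (see comments at each assertion).

test_that("Gibbs free energy obeys its defining identities and values", {
  ## dG(Tm) = 0 exactly, for any parameters
  set.seed(11)
  for (i in 1:25) {
    dHm <- runif(1, 6e4, 4e6); Tm <- runif(1, 300, 360)
    dCp <- runif(1, 0, 2e4)
    expect_identical(gibbs_free_energy(Tm, dHm, Tm, dCp), 0)
  }
  ## 400000 * (1 - 298.15/330) = 400000 * 31.85/330
  expect_equal(gibbs_free_energy(298.15, 4e5, 330), 400000 * 31.85 / 330,
               tolerance = 1e-12)
  expect_equal(gibbs_free_energy(298.15, 4e5, 330), 38606.06, tolerance = 1e-6)
  ## adding dCp = 5000: extra term 5000*(298.15 - 330 - 298.15*log(298.15/330))
  extra <- 5000 * (298.15 - 330 - 298.15 * log(298.15 / 330))
  expect_equal(gibbs_free_energy(298.15, 4e5, 330, dCp = 5000),
               38606.06 + extra, tolerance = 1e-6)
  expect_equal(gibbs_free_energy(298.15, 4e5, 330, dCp = 5000), 30661.13,
               tolerance = 1e-6)
})

test_that("equilibrium signal interpolates between the baselines", {
  p <- c(default_baselines(), dHm = 4e5, Tm = 330)
  pl <- as.list(p)
  ## at Tm half the molecules are unfolded: exact baseline midpoint
  mid <- ((pl$kN * 330 + pl$bN) + (pl$kU * 330 + pl$bU)) / 2
  expect_equal(equilibrium_signal(330, p), mid, tolerance = 1e-12)
  ## far below Tm the signal sits on the native baseline
  expect_equal(equilibrium_signal(293.15, p), pl$kN * 293.15 + pl$bN,
               tolerance = 1e-6)
  ## with unit flat baselines the signal IS the fraction unfolded,
  ## and the experimental back-calculation inverts the forward model
  f_direct <- equilibrium_signal(std_grid(), c(kN = 0, bN = 0, kU = 0, bU = 1,
                                               dHm = 4e5, Tm = 330))
  cv <- fixture_thermo_curve(dHm = 4e5, Tm = 330)
  f_back <- fraction_unfolded(cv, p)
  expect_lt(max(abs(f_back - f_direct)), 1e-10)
})

test_that("kinetic native fraction matches an independent ODE solve", {
  skip_if_not_installed("deSolve")
  grid <- seq(293.15, 368.15, by = 0.1)
  ## independent oracle: 4th-order Runge-Kutta on the log-state equation
  ## d(log x)/dT = -k_u(T)/v (same ODE, transformed so the explicit solver
  ## is not destabilized by the huge rates past the transition)
  rk4_xn <- function(Ea, Tf, v) {
    rhs <- function(T, y, parms)
      list(-(1 / v) * exp(-Ea / 8.314 * (1 / T - 1 / Tf)))
    u <- deSolve::ode(y = c(u = 0), times = grid, func = rhs, parms = NULL,
                      method = "rk4")[, "u"]
    exp(u)
  }
  set.seed(21)
  for (i in 1:4) {
    Ea <- runif(1, 1e5, 1e6); Tf <- runif(1, 310, 350); v <- runif(1, 0.5, 2)
    xn <- kinetic_xn(grid, Ea, Tf, v)
    expect_identical(xn[1], 1)                     # fully folded at scan start
    expect_true(all(diff(xn) <= 0))                # nonincreasing
    expect_true(all(xn >= 0 & xn <= 1))
    expect_lt(max(abs(xn - rk4_xn(Ea, Tf, v))), 1e-6)
  }
  ## doubling the scan rate leaves less time to unfold per kelvin
  x1 <- kinetic_xn(grid, 3e5, 340, v = 1)
  x2 <- kinetic_xn(grid, 3e5, 340, v = 2)
  expect_true(all(x2 >= x1))
  expect_error(kinetic_xn(rev(grid), 3e5, 340), "nonmonotonic")
})

test_that("kinetic signal mixes the baselines through the native fraction", {
  p <- c(default_baselines(), Ea = 3e5, Tf = 335)
  grid <- std_grid()
  y <- kinetic_signal(grid, p, v = 1)
  xn <- kinetic_xn(grid, 3e5, 335, 1)
  pl <- as.list(p)
  ## fully folded region lies on the native baseline
  pre <- xn > 1 - 1e-9
  expect_equal(y[pre], (pl$kN * grid + pl$bN)[pre], tolerance = 1e-7)
  ## fully unfolded region on the unfolded baseline
  post <- xn < 1e-9
  expect_equal(y[post], (pl$kU * grid + pl$bU)[post], tolerance = 1e-7)
  ## flat 0/1 baselines expose 1 - x_N directly
  flat <- kinetic_signal(grid, c(kN = 0, bN = 0, kU = 0, bU = 1,
                                 Ea = 3e5, Tf = 335), v = 1)
  expect_equal(flat, 1 - xn, tolerance = 1e-12)
})

test_that("the kinetic stability measure behaves like a pK", {
  ## k_u(Tf) = 1 by definition, so pku vanishes when Tf is the reference
  expect_equal(pku_std(3e5, 298.15), 0)
  ## -log10 exp(-(3e5/8.314)*(1/298.15 - 1/350)), independent arithmetic
  expect_equal(pku_std(3e5, 350),
               -log10(exp(-(3e5 / 8.314) * (1 / 298.15 - 1 / 350))),
               tolerance = 1e-12)
  expect_equal(pku_std(3e5, 350), 7.786485, tolerance = 1e-6)
  ## more stable (higher Tf) means slower unfolding at 25 C
  tf <- seq(300, 360, by = 5)
  expect_true(all(diff(pku_std(3e5, tf)) > 0))
})

test_that("the onset temperature is the root it claims to be", {
  ## the 50% 'onset' is the melting temperature itself
  expect_equal(as.numeric(t_onset(4e5, 330, onset_fraction = 0.5)), 330)
  ## self-consistency at the default 1%
  To <- t_onset(4e5, 330)
  f <- equilibrium_signal(as.numeric(To), c(kN = 0, bN = 0, kU = 0, bU = 1,
                                            dHm = 4e5, Tm = 330))
  expect_equal(f, 0.01, tolerance = 1e-4)
  expect_false(attr(To, "extrapolated"))
  ## steeper transitions start unfolding later (onset closer to Tm)
  onsets <- vapply(c(2e5, 4e5, 8e5), function(dh)
    as.numeric(t_onset(dh, 330)), numeric(1))
  expect_true(all(diff(onsets) > 0))
  ## an onset below the scan start is clamped and flagged
  To2 <- t_onset(1e5, 300, t_scan_min = 293.15)
  expect_equal(as.numeric(To2), 293.15)
  expect_true(attr(To2, "extrapolated"))
})

test_that("the Euclidean measure is the plane distance from the origin", {
  expect_equal(t_eucl(330, 320), sqrt(330^2 + 320^2), tolerance = 1e-12)
  expect_equal(t_eucl(330, 320), 459.6738, tolerance = 1e-6)
  expect_equal(t_eucl(330, 320), t_eucl(320, 330))
})

test_that("the neglected-dCp error is negative below Tm", {
  ## 5000*(298.15 - 330 - 298.15*log(298.15/330)), independent arithmetic
  expect_equal(dcp_neglect_error(5000, 298.15, 330), -7944.929,
               tolerance = 1e-6)
  expect_equal(dcp_neglect_error(0, 298.15, 330), 0)
  set.seed(31)
  for (i in 1:50) {
    Tm <- runif(1, 300, 370)
    Tref <- runif(1, 270, Tm - 1)
    expect_lt(dcp_neglect_error(runif(1, 100, 2e4), Tref, Tm), 0)
  }
  expect_error(dcp_neglect_error(5000, 340, 330), "below Tm")
})
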