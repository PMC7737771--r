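## Shared fixtures for the test suite: everything is generated in code.

std_grid <- function() seq(293.15, 368.15, by = 0.5)

## a clean mid-range thermodynamic curve
fixture_thermo_curve <- function(dHm = 4e5, Tm = 330, noise_sd = 0,
                                 seed = NULL, ...) {
  simulate_curve("thermodynamic", c(default_baselines(), dHm = dHm, Tm = Tm),
                 T_grid = std_grid(), noise_sd = noise_sd, seed = seed, ...)
}

fixture_kinetic_curve <- function(Ea = 3e5, Tf = 340, noise_sd = 0,
                                  seed = NULL, ...) {
  simulate_curve("kinetic", c(default_baselines(), Ea = Ea, Tf = Tf),
                 T_grid = std_grid(), noise_sd = noise_sd, seed = seed, ...)
}

## transition height of the default baselines at the grid midpoint
fixture_height <- function() {
  b <- default_baselines()
  tmid <- mean(range(std_grid()))
  abs((b[["kU"]] - b[["kN"]]) * tmid + (b[["bU"]] - b[["bN"]]))
}
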