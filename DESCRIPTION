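Package: meltcurve
Title: Quantitative Analysis of Protein Thermal and Chemical Unfolding Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sigmoidal protein unfolding curves from label-free thermal
    denaturation assays (NanoDSF intrinsic tryptophan fluorescence, circular
    dichroism, or any signal-versus-temperature readout) to three models of
    unfolding: an equilibrium two-state thermodynamic model (Gibbs-Helmholtz),
    an irreversible first-order kinetic model (Arrhenius, scan-rate aware) and
    an empirical two-temperature description.  Samples are ranked by
    single-number stability measures (apparent standard Gibbs free energy of
    unfolding, negative log of the standard-state unfolding rate constant, and
    the Euclidean combination of melting and onset temperatures), with
    covariance-based parameter uncertainties, a baseline-separation quality
    factor and reliability filtering.  Includes isothermal chemical
    denaturation analysis by linear extrapolation, heat-capacity estimation
    from the enthalpy-temperature dependence, plate-screen orchestration with
    stability heatmaps, and a synthetic-curve simulator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    readxl,
    optparse,
    withr
Config/testthat/edition: 3
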