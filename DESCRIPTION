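Package: chainrelax
Title: Hydrogen-Bond Chain Dynamics and Dielectric Relaxation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics studies of the
    Debye relaxation in hydrogen-bonding liquids such as methanol. Reads
    extended-XYZ and Tinker ARC trajectories, detects hydrogen-bonded chains
    geometrically, tracks chain identity and life-cycle events (birth, growth,
    shrinkage, death) across frames, estimates censored-exponential lifetime
    statistics, folds molecular observables onto the period of an applied
    sinusoidal electric field and fits in-phase/quadrature response
    amplitudes, and computes equilibrium dielectric spectra from polarization
    fluctuations via linear response. Includes seed-deterministic synthetic
    generators (rotational Brownian dipole ensembles, kinetic Monte Carlo
    chain dynamics, exact geometric fixtures) so every stage is testable
    without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    sandwich,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
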