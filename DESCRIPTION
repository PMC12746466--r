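Package: vibcascade
Title: Anharmonic Cascade Simulation of Hot Ground-State Cooling in
    Time-Resolved Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates equilibrium and time-resolved infrared spectra of
    polyatomic molecules from anharmonic vibrational data (mode frequencies
    and the anharmonicity X matrix). Provides Dunham-expansion energetics
    with occupation-dependent transition energies and intensities for
    fundamental, first-overtone and 1+1 combination bands; exact and grained
    Stein-Rabinovitch state counting for separable anharmonic oscillators;
    multicanonical flat-histogram sampling of vibrational occupation space
    with Boltzmann reweighting to canonical spectra; a one-parameter kinetic
    Monte Carlo simulator of vibrational cooling to an isothermal bath;
    initial-condition generators (surface-hopping geometry projection,
    thermal and statistical sampling); and band-shape and kinetic analysis
    of the resulting transient spectra (band integration, expectation
    frequency, sequential first-order fits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
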