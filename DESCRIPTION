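Package: neurophonon
Title: Neural-Phonon Modelling of EEG Dynamics with Stochastic
    Stuart-Landau Oscillator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates networks of noisy Stuart-Landau (Hopf normal form)
    oscillators as a model of multichannel EEG, maps their Fokker-Planck
    dynamics to effective drift and quantum-like potentials, and builds a
    phonon (normal-mode) description of collective amplitude fluctuations
    from the mass-weighted dynamical matrix.  Provides closed-form spectral
    observables (Green's-function mode spectra, cross-spectra, coherence,
    envelope correlations, phase-amplitude coupling strength, a 1/f
    background term) alongside their empirical counterparts computed from
    simulated or imported recordings (Welch power spectral density, band
    power, amplitude-amplitude coupling, phase-amplitude coupling,
    phase-locking value, coherence and coherence entropy), plus a
    rule-based classifier mapping model parameters to archetypal cognitive
    regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
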