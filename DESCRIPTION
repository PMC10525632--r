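Package: ipsotune
Title: Quadrupole Mass Spectrometer Auto-Tuning with an Annealed Multi-Weight Particle Swarm Optimizer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an improved particle swarm optimizer (I-PSO) that combines
    multiple inertia-weight proposals (linear, exponential, power and random
    schedules), per-particle dynamic position boundaries, and a simulated-annealing
    Metropolis rule for accepting regressions of the reported swarm best.  On top
    of the optimizer, the package provides a shifted/rotated benchmark-function
    suite for comparing the improved optimizer against standard PSO, a synthetic
    triple-quadrupole mass-spectrometer model (linear mass axis, offset-controlled
    peak width, Gaussian ion-source response surface with optional decoy mode),
    and the staged auto-tuning pipeline that alternates mass-axis and resolution
    calibration before optimizing ion-source and lens parameters for peak
    intensity.  All components are seeded and reproducible; spectra, iteration
    traces and tune reports are exportable as CSV and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
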