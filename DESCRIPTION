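Package: circlum
Title: Stochastic Modelling and Fitting of Light-Entrainable Cellular
    Circadian Clocks from Bioluminescence Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a minimal stochastic model of the light-entrainable
    cellular circadian clock: a three-variable transcription-translation
    negative feedback loop with protein-sequestration kinetics, a binary
    light input, and additive noise, integrated per cell by Euler-Maruyama
    and averaged over many independent cells to reproduce population-level
    bioluminescence reporter traces. Provides piecewise-constant lighting
    protocols, trace normalization (Z-score, adjusted Z-score), damped-sine
    fitting, peak/period/phase detection, a four-stage differential-evolution
    fitting pipeline that adjusts model parameters to plate luminescence
    recordings, post-fit analyses (phase response curves, phase-angle curves,
    single-cell phase histograms, PCA over fitted parameter ensembles), and a
    synthetic plate generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
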