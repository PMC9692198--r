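Package: cortnet
Title: Source-Space EEG Functional Connectivity Networks in Infant Sleep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for frequency-specific cortical activity
    networks estimated from high-density scalp EEG during N2 sleep.
    Implements a geometric 25-band Kaiser FIR filter bank, spherical-spline
    bad-channel interpolation, automated sleep-spindle detection with
    cross-channel power gating and spindle excision, a spherical-head
    forward model with a dSPM minimum-norm inverse collapsed to cortical
    parcels, amplitude (orthogonalized envelope correlation) and phase
    (debiased weighted phase-lag index) adjacency matrices, simulation-based
    fidelity pruning of unresolvable parcel pairs, and nonparametric
    group statistics (Kruskal-Wallis, edge-wise one-tailed Wilcoxon with
    Benjamini-Hochberg correction, network density). A synthetic-data
    generator produces sensor EEG with known envelope/phase couplings,
    sleep spindles, and cohort group structure so that every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
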