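Package: MEAactivity
Title: Activity, Burst, and Network-Event Analysis for Multiwell
    Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spike-list recordings from multiwell
    microelectrode arrays (MEAs) of cultured neuronal networks. Reads
    per-spike event tables (Axion Maestro style CSV), applies activity-based
    electrode and well inclusion criteria, detects per-electrode bursts with
    the max-interval method, detects synchronous network spikes and network
    bursts, assembles per-well per-day activity features (mean firing rate,
    burst rate and duration, inter-burst interval, network-event rates,
    percentages of spikes in bursts and network events), and compares
    experimental groups with nonparametric statistics: per-day Mann-Whitney U
    tests combined by Fisher's method, and a pooled-window Mann-Whitney U test
    calibrated by permutation of well labels. A doubly stochastic point-process
    simulator generates complete synthetic experiments for end-to-end testing,
    null calibration, and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
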