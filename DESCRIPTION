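Package: layerquartet
Title: Laminar fMRI Analysis of Bistable Motion-Quartet Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of mesoscopic, depth-resolved fMRI
    responses to the bistable motion quartet. Provides frame-accurate
    stimulus and percept-report schedule generation, a ground-truthed
    synthetic laminar BOLD generator with a linear draining-vein
    (macrovascular leakage) component, percent-signal-change GLM
    estimation with AR(2) prewhitening, percentile-based winner-take-all
    cluster mapping, cosine-similarity condition specificity, equivolume
    laminar and differential-profile analysis with slope tests, and
    event-related averaging of percept-locked responses, together with
    exact small-sample Wilcoxon signed-rank group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
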