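Package: patchstats
Title: Patch-Clamp Feature Extraction, Synaptic Event Detection, and
    Cohort Statistics for Hippocampal Aging Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-cell patch-clamp recordings from
    hippocampal CA1 pyramidal neurons and the cohort-level statistics used in
    aging studies of intrinsic excitability. Extracts passive membrane
    properties, action-potential waveform metrics, firing metrics and the
    post-burst afterhyperpolarization (AHP) from current-clamp step protocols;
    detects spontaneous excitatory postsynaptic currents (sEPSCs) in
    voltage-clamp traces by scaled-template matching with recording quality
    control; and provides the accompanying statistical battery (Grubbs outlier
    screening, one-way and repeated-measures ANOVA with Tukey HSD, Pearson
    correlation panels, water-maze block averaging, delayed-matching-to-place
    improvement, 2^-ddCt relative quantification and densitometry fold
    changes). Includes an adaptive exponential integrate-and-fire simulator
    and Poisson event-train generator that produce recordings with known
    ground truth, so every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
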