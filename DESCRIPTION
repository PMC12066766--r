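Package: nirsgraph
Title: Task fNIRS Preprocessing, ROI Activation, Functional Connectivity and
    Weighted Brain-Graph Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for multi-channel continuous-wave
    functional near-infrared spectroscopy (fNIRS) recordings from psychomotor
    training experiments. Converts two-wavelength raw intensities to optical
    density, applies kurtosis-based wavelet and hybrid spline/Savitzky-Golay
    motion-artifact correction, zero-phase band-pass filtering, and the
    modified Beer-Lambert law to obtain oxy-/deoxy-hemoglobin concentration
    changes. Computes trial-wise baseline-corrected region-of-interest
    activation, thresholded Pearson functional connectivity with Monte Carlo
    calibration of the spuriousness threshold, weighted graph-theory metrics
    (global efficiency, local efficiency, clustering coefficient, Louvain
    modularity), and the factorial group-level statistics applied to them
    (Shapiro-Wilk gating, type-III two-way ANOVA with partial eta squared,
    aligned-rank-transform factorial ANOVA, Spearman correlation, Bonferroni
    adjustment, pairwise contrasts). Includes a synthetic cohort generator
    with injectable group-by-sex effects so every stage is testable without
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
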