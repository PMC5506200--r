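Package: homonet
Title: Weighted Motor-Network Analysis of Task fMRI with Homotopic Connectivity Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for block-design task-fMRI functional connectivity analysis
    of weighted brain networks, with an emphasis on interhemispheric (homotopic)
    organisation. Builds HRF-convolved block regressors, extracts spherical-ROI
    BOLD time series from 4D volumes, denoises them (bandpass plus nuisance
    regression), computes condition-weighted Pearson correlations with Fisher
    transformation, runs second-level random-effects edge tests with FDR
    control, and derives weighted graph metrics (strength, shortest paths on
    D = 1 - W, betweenness, global efficiency, clustering, assortativity,
    Louvain modularity, small-world indices). Its core statistics quantify
    homotopic symmetry: strongest-link anchoring of each region to its
    contralateral homolog, within-module homotopic pairing, per-module symmetry
    ratios, and permutation / exact-enumeration chance nulls. A synthetic
    multi-subject BOLD generator with planted homotopic, intrahemispheric and
    background coupling makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
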