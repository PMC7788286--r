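Package: dubscreen
Title: Pooled In Vivo shRNA Screen Simulation, Deconvolution and Hit Calling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pooled in vivo shRNA dropout/enrichment screens in
    hematopoietic stem and progenitor cells: a synthetic screen simulator
    with an explicit engraftment bottleneck and per-gene fitness effects,
    exact-match hairpin deconvolution from FASTQ reads, library
    representation QC, empirical-Bayes moderated differential abundance
    against the input (T0) condition, and two-tier gene-level hit calling
    (per-shRNA thresholds, median fold-change consolidation, multi-screen
    replication and opposite-effect exclusion). Also implements an AP-MS
    interactome filtering scheme with Gaussian-downshift imputation of
    missing label-free intensities and cross-condition consensus calling
    of bait interactors against IgG controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
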