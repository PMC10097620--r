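Package: dimerscope
Title: Differential Interactome Analysis for Dimerizer-Controlled AP-MS
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of affinity-purification mass-spectrometry
    (AP-MS) label-free quantification experiments built around chemically
    controlled RAF kinase dimerization. Reads MaxQuant proteinGroups tables,
    applies category and valid-value filters, imputes left-censored missing
    values (per-column downshifted Gaussian or condition-wise log-normal),
    calls differential interactors with right-tailed t-tests plus
    Benjamini-Hochberg and fold-change thresholds or with an s0-modified
    statistic under a permutation-based false discovery rate with a volcano
    cutoff curve, fits per-protein linear models on a one-hot experimental
    design with coefficient contrasts, and provides principal-component
    quality control, interactor overlap matrices and reference-list
    comparison. Includes a synthetic-data generator with known ground truth
    that emulates the 16-condition, 3 x 2 replicate study layout so the full
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
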