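Package: drebic
Title: Drug Response Evaluation from Pooled CRISPR Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of pooled CRISPR knockout viability screens and
    expression-based drug-response prediction. Turns sgRNA count tables (or
    raw amplicon FASTQ reads) into normalized abundances, guide-level log
    fold changes and z-scores, and gene-level CRISPR viability scores with
    Kolmogorov-Smirnov significance and replicate-consistent hit calling.
    Combines viability scores with basal gene expression into per-sample
    DREBIC drug-sensitivity scores, and evaluates predictions against
    measured IC50 response via responder stratification, ROC/AUC,
    permutation null models, gene-set size optimization and
    mutation-stratified response deltas. Also fits Chou-Talalay
    median-effect curves and computes combination indices for
    constant-ratio drug combinations, and ships a seed-deterministic
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
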