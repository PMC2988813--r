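Package: rbpscreen
Title: Screening for RNA-Binding Proteins with Protein Microarrays and
    RIP-Chip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-scale screens of RNA-binding
    proteins (RBPs) in yeast. Selects candidate binders from replicate
    protein-microarray probings either by replicate Z-scores (single-RNA
    probes) or by median percentile ranks with an automatically detected
    bimodal-trough cutoff (complex RNA pools); calls in vivo RNA targets
    from RIP-Chip experiments against mock controls with quality filters
    and a Bayesian regularized t-statistic; tests gene sets for GO and
    Pfam over-representation with exact hypergeometric statistics and
    Bonferroni correction; analyses replicate overexpression profiles for
    coordinated shifts of a target set; and clusters candidate-RBP
    expression profiles across condition compendia. Ships generators for
    synthetic datasets with known ground truth so every stage can be
    validated by parameter recovery and null calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
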