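Package: comutkit
Title: Mutual-Exclusivity Screens, Pathway Permutation Tests and
    Enrichment Concordance for Somatic Alteration Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrative statistics for dissecting co-mutation structure
    between cancer driver genes. Builds binary alteration matrices from
    MAF-style mutation calls and GISTIC copy-number calls, runs stratified
    two-by-two Fisher exact mutual-exclusivity/co-occurrence screens with
    conditional-MLE odds ratios, tests keyword-tagged pathway activation
    against an empirical null of random pathway subsets, quantifies
    cross-comparison concordance of normalized enrichment scores (quadrant
    counts, hypergeometric overlap, correlations, phi, Fisher-Z), performs
    n-gram term over-representation on gene-set names, annotates binding
    peaks to promoter-proximal transcription start sites, and ships a
    synthetic-data generator that plants known odds ratios, activation
    shifts, overlap counts and binding fractions so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
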