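Package: clonemut
Title: Off-Target and De Novo Mutation Analysis for Cloned, Gene-Edited Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clone-based analysis pipeline for detecting CRISPR-Cas9
    off-target mutations and classifying de novo mutations (heterozygous
    versus mosaic) in gene-edited versus control cloned animals. Implements
    staged presence/absence filtering of multi-sample variant calls, an
    exact binomial allele-dosage test with Bonferroni control for mosaicism,
    guide-homology off-target site scanning with PAM constraints,
    mutation-spectrum and developmental-stage attribution, two-proportion
    z-tests and exact Fisher tests for group comparisons, read-level
    three-haplotype support checks, and a fully truth-labelled synthetic
    clonal-study simulator so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
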