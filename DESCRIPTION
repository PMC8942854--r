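Package: substiscan
Title: Detection and Cohort Analysis of Tryptophan Codon-Reassignment Substitutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting tryptophan-to-phenylalanine (W>F) and other
    tryptophan codon-reassignment peptides ("substitutants") in shotgun
    proteomics cohorts. Builds tryptophan-substituted protein search
    databases and reporter-construct search spaces, performs in-silico
    tryptic digestion with standard engine constraints, calls substitutant
    peptides from reference-normalized peptide evidence tables using
    site-spanning, uniqueness, positivity and reproducibility filters, and
    computes cohort-level statistics: per-sample event counts, IDO1
    stratification with Wilcoxon rank-sum tests, per-gene high/low
    expression counting, W>F enrichment over the average W>X background,
    tumour-type classification, and weighted Kolmogorov-Smirnov gene-set
    enrichment with a permutation null. A synthetic-cohort generator with
    known ground truth (IDO1-dependent W>F in tumours over a uniform W>X
    background) makes every stage testable without access to raw proteomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
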