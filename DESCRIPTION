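Package: synsel
Title: Quantifying Negative Selection on Synonymous Variants with
    Singleton-Based Constraint Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring purifying selection on synonymous
    single-nucleotide variants from population allele-frequency data.
    Implements the mutability-adjusted proportion of singletons (MAPS)
    statistic and its square-root-recalibrated variant (TRAPS), with
    Wilson-type binomial confidence intervals and Welch contrasts;
    per-codon optimality metrics (codon stability coefficient, tRNA
    adaptation index with wobble-pairing weights, GC content) and
    per-substitution deltas; downstream comparative analyses (optimality
    contrasts by amino acid, GERP rank tests, saturation of
    optimality-reducing changes, constrained-gene and ClinVar subsets,
    SpliceAI splice classes, predictor quartiles); a cross-validated
    LASSO decomposition of selection scores into codon-level predictors;
    and a deterministic synthetic-data generator producing gnomAD-like
    variant tables with known planted selection for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
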