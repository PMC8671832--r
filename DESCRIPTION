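Package: tadsv
Title: TAD-Aware Clinical Interpretation of Structural Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretation support for balanced and unbalanced structural
    variants using topologically associated domains (TADs) as the unit of
    analysis.  Resolves breakpoints to TADs and flanking TADs, annotates
    genes, regulatory-interaction clusters and chromatin loops with
    disruption and position-effect flags, computes information-content
    phenotype similarity (PhenSSc, MaxSSc) with a permutation p-value
    against disorder term sets, performs reciprocal-overlap matching of
    copy-number variants against curated databases, scores CNVs with an
    automated ACMG dosage rubric, classifies balanced variants with a
    rule engine, and assembles ISCN-labelled report tables.  All inputs
    are local tab-separated annotation files; a seeded fixture generator
    produces a complete miniature input universe for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
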