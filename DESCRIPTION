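Package: synsig
Title: Significance Analysis of Synonymous Mutation Enrichment in Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("synsig", "developers", email = "synsig@example.org", role = c("aut", "cre"))
Description: Detects genes enriched for synonymous (or, in a quality-control
    mode, non-synonymous) somatic mutations in cancer cohorts against a
    non-coding background model built from intronic and untranslated-region
    mutations. The background corrects for patient-, histology-, and
    gene-level mutational heterogeneity using per-cohort marginal rate
    factors and covariate-nearest-neighbour gene "bagels" pooled under a
    beta-binomial compatibility test. Per-gene significance is computed by
    category ranking, 2D projection, and discrete convolution of per-patient
    score distributions; candidates are called by an empirical-Bayes local
    false discovery rate (or Benjamini-Hochberg in the quality-control
    mode). Also includes per-patient synonymous rate descriptives, a
    permutation test for mutation clustering in protein motifs, and a
    synthetic cohort generator so the whole pipeline is testable at toy
    scale without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
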