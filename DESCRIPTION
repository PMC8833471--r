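Package: pgrspipe
Title: Polygenic Risk Scoring and Acid-Exposure Expression Screening for
    Barrett's Esophagus Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for case-control susceptibility studies of
    Barrett's esophagus and related esophageal phenotypes. Computes additive
    polygenic risk scores over literature-derived risk loci (with published or
    in-sample odds-ratio weights), per-SNP case/control allele association with
    Fisher's exact test, nonparametric comparison of score distributions across
    patient groups, RPKM/TPM normalization of gene-level counts, a
    threshold-based differential-expression filter with Benjamini-Hochberg FDR,
    exposure-versus-baseline gene-set subtraction, hypergeometric gene-set
    over-representation with a directional z-score, and cross-experiment
    pathway-overlap tables. Includes a synthetic-data generator (Hardy-Weinberg
    genotypes, negative-binomial counts with planted effects) so every stage is
    testable without access to individual-level patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
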