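Package: aminoMR
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: A complete two-sample Mendelian randomization (MR) workflow for
    GWAS summary statistics, developed around the question of whether
    genetically predicted circulating amino acid levels affect the risk of
    metabolic dysfunction-associated fatty liver disease (MAFLD). Provides
    z-score to effect-size conversion for standardized traits, instrument
    selection by multiplicity-adjusted significance and greedy LD clumping,
    proxy-variant substitution, effect-allele harmonization with palindromic
    variant policies, causal estimators (Wald ratio, fixed- and multiplicative
    random-effects inverse-variance weighting, MR-Egger regression, weighted
    median, weighted mode), instrument-strength and heterogeneity diagnostics,
    fixed-effect meta-analysis across discovery and replication cohorts,
    reverse-direction MR, continuous-outcome validation, and a seeded
    synthetic summary-statistics generator with known causal ground truth for
    calibration and robustness studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
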