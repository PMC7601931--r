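Package: cllassoc
Title: Case-Control SNP Association and Genotype-Phenotype Analysis for
    CLL Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for candidate-gene case-control studies
    of chronic lymphocytic leukaemia (CLL): Hardy-Weinberg departure
    estimation with asymptotic confidence intervals and an exact
    conditional test, genotype-distribution chi-squared tests,
    Haldane-Anscombe-corrected odds ratios with Woolf intervals under
    codominant, dominant, recessive and allelic models, planned linear
    contrasts with alerting and effect-size correlations, a
    bootstrap-calibrated F null, the Sn robust scale estimator, Fisher's
    LSD homogeneous-group notation, and a fully parameterised synthetic
    cohort generator for end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
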