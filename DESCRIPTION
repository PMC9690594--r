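Package: tgslift
Title: Total Genotype Scores for Weightlifting and Power-Athlete Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control single-nucleotide polymorphism association under
    collapsed genetic models (dominant, recessive, allele, genotypic),
    Hardy-Weinberg equilibrium testing, and construction of polygenic total
    genotype scores (TGS) for strength and power athlete cohorts. Ships the
    published genotype-count tables for a panel of twelve strength-related
    autosomal polymorphisms in Japanese weightlifters and controls, a
    data-driven builder for a weightlifting-related score model, exact TGS
    distributions by convolution over independent loci, group-level inference
    (t-test, ANOVA with linear trend, TGS-performance regression), and a
    calibrated synthetic-cohort generator so that every pipeline stage can be
    exercised without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
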