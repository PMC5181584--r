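Package: gxwqtl
Title: Genotype-by-Watering-Regime Association Mapping in Structured Diploid Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect genotype-by-watering-regime interactions for
    quantitative traits in structured association panels of highly homozygous
    diploids such as small-fruited tomato. Provides replicate-level variance
    dissection (sequential ANOVA, broad-sense heritability, plasticity indices,
    interaction partitioning into re-ranking and scale change), genotype quality
    control (missingness and minor-allele-frequency filters, mean-dosage
    imputation, identity-by-state kinship, principal co-ordinate structure axes,
    composite linkage disequilibrium), a multi-locus mixed-model scan with
    forward cofactor selection, a bivariate multi-trait mixed model with global
    and interaction tests for two watering regimes, LD-based QTL confidence
    intervals with gene counts, QTL-type classification (constitutive, regime
    specific, differential, antagonist), cross-population QTL overlap, and a
    structured-panel simulator with known QTL architecture for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
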