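Package: polygrowth
Title: Polygenic Adaptation Analysis of Plant Growth Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for dissecting the genetic basis and
    adaptive differentiation of plant rosette growth. Fits three-parameter
    logistic growth curves to per-plant diameter time series, computes
    design-corrected genotypic means, growth plasticity (GxE) residuals and
    broad-sense heritability, runs EMMA/EMMAX-style mixed-model genome-wide
    association on SNP and loss-of-function markers with identity-by-state
    kinship, builds LD-clumped polygenic scores with the Qx over-dispersion
    test of Berg and Coop, contrasts quantitative-trait Qst against the
    genome-wide SNP Fst distribution with permutation and multivariate-normal
    neutral nulls, and tests GO-term enrichment of associated genes with a
    permutation-calibrated significance threshold. A synthetic-data module
    simulates structured selfing populations, polygenic traits and growth
    experiments so that every stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    nlme,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    vcfR,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
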