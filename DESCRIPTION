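Package: phenoload
Title: Gene-Level Variant-Load Outlier Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a gene-level rare-variant load analysis for
    case-control cohorts of common, late-onset conditions such as
    age-related hearing loss. Annotated variants are filtered to a
    qualifying set (minor allele frequency below a threshold under a
    configurable population mode, plus high predicted impact by
    pathogenicity, splice, or 5'UTR predictors); per-gene qualifying-variant
    loads in the two phenotype groups are related by ordinary least-squares
    regression; genes whose residuals fall outside six interquartile
    distances beyond the residual quartiles are called directional outliers;
    and outlier lists are tested for hypergeometric enrichment in curated
    gene sets with multiple-testing adjustment. A fully synthetic cohort and
    variant generator with planted signal genes, planted variable genes,
    and tunable case-to-control phenotype misclassification supports
    end-to-end testing and an experiment module that quantifies how control
    group contamination degrades signal-gene recovery and enrichment.
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
    optparse
Config/testthat/edition: 3
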