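Package: gwasmodels
Title: Multi-Panel Imputation Combination and Non-Additive Case-Control GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for comprehensive case-control genome-wide association
    analysis beyond the additive model. Combines genotype-imputation results
    from multiple reference panels by best info score, runs logistic
    association tests under five inheritance models (additive, dominant,
    recessive, heterodominant, genotypic) with covariates and full
    X-inactivation handling, applies marker and post-association quality
    control, collapses significant variants into loci and classifies their
    inheritance via a dominance-deviation test, builds approximate-Bayes-factor
    credible sets, performs fixed-effect meta-analysis, and computes
    inheritance-model-specific power and required sample sizes. Includes a
    synthetic cohort generator so every stage can be exercised end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
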