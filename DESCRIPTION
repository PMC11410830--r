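Package: gcfmix
Title: Multi-Factor Global Change Experiments: Design, Null Models and
    Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing experiments in which many
    global change factors (GCFs) act on soil systems simultaneously.
    Provides randomized factor-pool experimental designs, nonparametric
    bootstrap effect sizes with Benjamini-Hochberg correction, effect-based
    factor dissimilarity indices with ordination and clustering views,
    bootstrap null-model predictions of joint multi-factor responses under
    additive, multiplicative and dominative assumptions, classification of
    net synergistic and antagonistic interactions from rescaled deviations,
    a seven-model hierarchical framework separating factor-identity effects
    from number-of-factors and dissimilarity effects, and a synthetic
    microcosm data generator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vegan
Config/testthat/edition: 3
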