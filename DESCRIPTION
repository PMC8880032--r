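Package: diallelkit
Title: Quantitative Genetics of Partial Diallel Trials: REML, Heterosis
    and Combining Ability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-environment hybrid breeding
    trials laid out as an incomplete (partial) male-by-female diallel.
    Provides restricted maximum likelihood (REML) estimation of variance
    components with genotype BLUEs and BLUPs, broad- and narrow-sense
    heritability, least significant differences and genotypic
    coefficients of variation, trait correlation matrices, mid- and
    best-parent heterosis with contrast-based significance tests, and
    general/specific combining ability (GCA/SCA) estimation for the
    realized crosses of a partial diallel. A synthetic-trial generator
    with known genetic truth (GCA, SCA, genotype-by-environment, block
    and residual effects, plus correlated male floral traits and seed
    set) makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
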