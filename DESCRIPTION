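Package: heteropattern
Title: Genome-Based Discovery of Heterotic Patterns for Hybrid Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for establishing heterotic patterns in hybrid breeding
    programs from genomic and multi-location field-trial data. Implements
    REML analysis of augmented hybrid trials with GCA/SCA variance
    decomposition, broad-sense heritability and likelihood-ratio tests;
    ridge-regression BLUP (RR-BLUP) prediction of single-cross performance
    with additive and dominance marker effects via Henderson's mixed-model
    equations; chess-board cross-validation over relatedness scenarios;
    simulated-annealing identification of complementary heterotic groups
    from the predicted full diallel; and short- and long-term evaluation of
    candidate patterns by hybrid performance, theoretical selection limit
    under reciprocal recurrent selection, and genetic representativeness.
    A configurable generator of synthetic breeding programs (divergent
    parental pools, unbalanced factorials, augmented trial designs)
    supports validation without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
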