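Package: tetramap
Title: Tetrad Analysis and Crossover Interference Statistics for Budding Yeast
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies dissected four-spore meiotic tetrads into parental
    ditype, tetratype and non-parental ditype configurations, estimates
    genetic map distances with the Perkins equation and multinomial
    standard errors, quantifies crossover interference through the ratio
    of observed to Papazian-expected non-parental ditypes, computes
    recombination frequencies from random-spore platings, and tallies
    gene-conversion (non-Mendelian segregation) events and spore
    viability.  Tetrad genotypes are held in a TetradExperiment container
    built on SummarizedExperiment.  A meiosis simulator with a
    gamma-renewal (counting) model of crossover interference generates
    synthetic tetrad datasets so that every estimator can be validated by
    parameter recovery.  Exact two-tailed Fisher and Mann-Whitney tests
    used for cytological count and length comparisons are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Genetics, Software, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
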