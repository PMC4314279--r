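Package: ophrysim
Title: Two-Locus Pollinator Attraction and Speciation Dynamics in Ophrys Orchids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how allelic variation at the desaturase genes SAD2 and SAD5
    shapes floral alkene composition, pollinator attraction, and pollinator-mediated
    speciation in the sexually deceptive orchids Ophrys sphegodes and O. exaltata.
    Provides a synthetic-data generator for allelic expression/scent tables and
    pollinator-choice experiments, stepwise-AIC linear models linking expression to
    7-, 9- and 12-alkene amounts, permutation-resampled Poisson regressions of
    pollinator visits on scent, a genotype-level attraction landscape with
    confidence-interval perturbation and an optional dominant suppressor locus,
    and a discrete-generation stochastic simulation of pollinator-driven
    divergence between the two species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
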