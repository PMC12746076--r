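Package: raptormech
Title: Hindlimb Lever Mechanics and Tendon Tensile Properties of Raptorial Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative biomechanics of the raptorial ankle
    dorsiflexion mechanism. Implements third-class lever models of the
    m. tibialis cranialis system (resistance of prey, required muscle force,
    mechanical advantage, torque), tarsometatarsus morphometric summaries
    with nonparametric group comparisons, processing of cyclic tensometer
    load-displacement traces into stress-strain hysteresis loops, regional
    elastic moduli and resilience, and first-principles phylogenetic
    comparative statistics (Brownian variance-covariance, Pagel's lambda
    maximum likelihood, PGLS ANOVA/MANOVA with residual-randomization
    permutation). A synthetic-data module generates tensometer traces with
    known constitutive parameters, morphometric specimen populations and
    Brownian-motion traits on trees, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
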