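Package: priceparts
Title: Temporal Price-Equation Partitioning of Community Biomass Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions temporal change in community function (arthropod
    biomass) between paired community samples into five additive components
    of community (dis-)assembly - species richness loss and gain, species
    identity loss and gain, and abundance change of persisting species -
    using the ecological (CAFE) form of the Price equation. Provides
    allometric length-mass biomass estimation, within-year replicate
    synthesis by Poisson splitting and bootstrap, pairwise comparison
    designs (fixed baseline, moving average, restricted moving average,
    intra-annual controls), resampling inference over no-reuse subsets with
    linear mixed-effects models, sample-coverage diagnostics, occupancy
    filters, and a synthetic grassland arthropod community generator with a
    Monte-Carlo oracle for the expected partition components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
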