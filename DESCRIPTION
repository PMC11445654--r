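Package: nitrokinetics
Title: Kinetic Modeling of Homogeneous Mixed-Acid Nitration in Continuous Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kinetic modeling of homogeneous nitration under mixed
    sulfuric/nitric acid in continuous-flow reactors. Implements
    integral-method reaction-order inference, apparent second-order rate
    constant estimation from conversion-time series via the excess-reagent
    transform, decomposition of apparent rate constants into nitronium-based
    intrinsic kinetics through a Marziano-type activity-coefficient function
    and a two-stage empirical nitronium-fraction model, Arrhenius parameter
    extraction, forward conversion prediction with extrapolation flagging,
    response-surface generation, validation against experiments, and
    grid-search optimization of reaction conditions. A synthetic-data
    generator produces conversion-time campaigns and nitronium tables from
    known ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
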