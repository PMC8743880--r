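Package: domstrat
Title: Strategic Targeting of Dominance Interactions in Animal Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting strategic, cost-dependent targeting of
    dominance interactions in animal social groups. Implements randomized-Elo
    hierarchy inference on split interaction data, a subgroup-composition
    constrained permutation null model, the "tendency to interact" statistic
    with smoothing-spline confidence bands from repeated data splits, and a
    Bayes-rule analysis of how higher- versus lower-cost aggression is
    allocated across rank differences. Includes an agent-based simulator of
    fission-fusion groups with known latent ranks for validating the full
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    mgcv
Config/testthat/edition: 3
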