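Package: socnetqap
Title: Temporal Social Network Autocorrelation and Territory-Manipulation
    Analysis for Group-Living Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing daily directed interaction networks of
    shell-dwelling cichlid communities and the consequences of experimental
    territory augmentation. Builds per-community, per-day weighted networks
    from dyadic interaction records; tests temporal network autocorrelation
    with a community-restricted quadratic assignment procedure (label swaps
    confined to Walktrap sub-groups); fits Poisson-lognormal mixed models of
    sex-partitioned degree with least-squares-means contrasts; and analyses
    territory-loss and group-membership outcomes of a nine-arm shell
    manipulation experiment with MAP Bayesian regression and planned,
    FDR-corrected contrasts. Includes a seeded synthetic-data generator
    emulating the study design so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    emmeans,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
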