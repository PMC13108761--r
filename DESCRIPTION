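Package: gmltwin
Title: Digital-Twin Normative Modelling of Regional Brain Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Normative modelling of regional brain morphometry with
    nearest-neighbour digital twins. Simulates seeded synthetic cohorts of
    healthy controls, radiologically isolated syndrome (RIS) and multiple
    sclerosis (MS) subjects with planted structural deviations, embeds a
    healthy reference on a low-dimensional manifold, reconstructs a
    subject-specific healthy "digital twin" from the 30 nearest reference
    neighbours, and scores per-region deviations (GeoNorm z-scores) against
    leave-one-out local variability together with a brain age gap. Downstream
    tooling covers abnormal-region burden maps, rank-based group comparisons
    with top-region ranking, k-means risk clustering of RIS subjects with
    bootstrap confidence intervals and exact 2x2 tests, multinomial cluster
    membership models, and pseudo-temporal trajectory fits of regional
    z-scores along graph-geodesic progression scores.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mgcv,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
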