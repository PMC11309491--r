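Package: cellalign
Title: Agent-Based Simulation of Collectively Aligning Elliptical Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Energy-derived agent-based model of collective alignment in
    populations of actively moving elliptical cells. Cells self-propel,
    avoid mutual overlap via forces and torques computed from the boundary
    intersection points of ellipse pairs, optionally deform their aspect
    ratio at fixed area, and form deterministic front/back cell-cell
    junctions through which supracellular actin bundles transmit aligning
    torques. Includes exact ellipse-ellipse intersection geometry, an
    explicit-Euler engine with periodic boundaries, population observables
    (nematic order, packing fraction, contact statistics, alignment length
    scale, junction-graph degree analysis) and ensemble sweep drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
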