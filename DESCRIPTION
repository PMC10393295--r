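Package: lamcsd
Title: Laminar Current-Source-Density Pattern Analysis and Forward Modeling
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing visually evoked laminar current source
    density (CSD) patterns and population spiking from multichannel
    extracellular recordings, and for comparing them across animals and
    against models. Implements delta inverse-CSD estimation with a disc
    forward operator, an exact Wasserstein (earth mover's) distance between
    sink/source-normalized CSD patterns, principal-component extraction of a
    cohort-level canonical pattern, Kolmogorov-Smirnov similarity and
    correlation statistics on population firing rates, a synthetic-cohort
    generator for flash-evoked Neuropixels-like data, and a desk-scale
    laminar rate-network model with depth-resolved synaptic placement and
    conserved return currents.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
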