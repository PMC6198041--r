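Package: mbex
Title: Mushroom Body Extinction Circuit Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for Drosophila mushroom-body memory-extinction
    studies. Provides EM-skeleton morphometry (SWC trees, Strahler order,
    geodesic distances, dendritic-root inference, axonlet extraction),
    synapse-placement statistics (geodesic distance profiles, Gaussian vs
    bimodal-Gaussian mixture selection by BIC, detection-rate-corrected
    synapse-count bounds, connectivity tables, dendrogram layouts),
    calcium-imaging quantification (dF/F0, odor-response AUC, per-fly
    normalization, normality-gated paired statistics), T-maze behavioral
    scoring and conditioning-protocol timelines, a compartmentalized
    KC-to-MBON rate model with dopamine-gated synaptic depression and
    placement-dependent feedforward inhibition, and seeded synthetic-data
    generators with planted ground truth for end-to-end validation.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
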