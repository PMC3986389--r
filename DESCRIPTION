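Package: restenosim
Title: Agent-Based Simulation of In-Stent Restenosis in an Artery Cross-Section
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional lattice agent-based model of the vascular
    response to balloon angioplasty plus bare-metal stent deployment.
    Starting from a post-procedural vessel cross-section, stochastic
    behavioural rules for platelets, leukocytes, smooth muscle cells and
    endothelial cells, coupled through diffusing TGF-beta and TNF-alpha
    cytokine agents, reproduce neointimal hyperplasia and in-stent
    restenosis. The package provides scenario configuration, single- and
    overlapping-stent geometries, replicate harnesses, lumen-diameter and
    percent-area-change measurement protocols, tidy time-series output and
    ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
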