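Package: a2amsm
Title: Markov State Modelling of Adenosine A2A Receptor Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for reconstructing G-protein coupled
    receptor activation from molecular-dynamics-style trajectory data.
    Computes the two classic A2A activation descriptors (the R3.50-E6.30
    ionic-lock distance and the RMSD of Y7.53 from its inactive position),
    runs goal-oriented adaptive sampling campaigns on a calibrated
    synthetic activation landscape, estimates reversible Markov State
    Models with PCCA+ macrostates and bootstrap population uncertainties,
    decomposes activation pathways with transition path theory, and maps
    cholesterol occupancy free-energy hotspots on a 1 Angstrom grid.
    Ships calibrated synthetic generators (Langevin landscape sampler,
    reversible six-state kinetic chain, biased lipid-diffusion scenes) so
    the whole pipeline is testable without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    methods,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
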