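Package: piezotraj
Title: Trajectory Analytics for Pressure Adaptation of Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for studying pressure adaptation
    of proteins from molecular-dynamics trajectories. Implements block-averaged
    fluctuation statistics (heavy-atom and C-alpha mean-square fluctuations,
    radius of gyration), a two-stage quasiharmonic analysis of the protein
    potential energy landscape yielding intrinsic expansivity, compressibility
    and glass-transition parameters from a pressure-temperature grid of
    fluctuations, geometric hydrogen-bond detection with equivalent-donor
    merging and occupancy networks, and grid/Monte-Carlo cavity-and-cleft
    volumetrics with void tracking and merge detection. Ships a synthetic
    trajectory generator so every stage is testable without running molecular
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
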