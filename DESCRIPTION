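Package: monomix
Title: Analysis of Mixed Fatty-Acid Langmuir Monolayers at Aqueous Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing mixed fatty-acid monolayers used as proxies
    for sea-spray-aerosol interfaces. Implements a surface-pKa
    Henderson-Hasselbalch protonation model for assigning acid/base states at
    a chosen pH, a synthetic monolayer generator (hexagonal headgroup
    lattices with controllable lateral mixing, vertical headgroup staggering
    and desorption), graph-network metrics of lateral molecular aggregation
    (2D-periodic radial distribution functions, distance-cutoff neighbour
    graphs, node degree and average pairwise connectivity), interface
    structure analyses (vertical headgroup deviations, z-density profiles,
    geometric hydrogen-bond counting), and a weighted histogram analysis
    method (WHAM) implementation that reconstructs potentials of mean force
    from umbrella-sampling windows, with an overdamped Langevin sampler for
    generating synthetic windows. Reads and writes GRO, PDB and XYZ
    coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    bio3d,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
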