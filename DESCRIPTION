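Package: npcvoid
Title: Void Statistics, Percolation and First-Passage Kinetics of Passive
    Transport Through the Nuclear Pore Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing passive transport of globular proteins through
    the nuclear pore complex (NPC) from ensembles of disordered, bead-per-residue
    FG-nucleoporin mesh configurations.  Implements probe-size-dependent void
    (accessible-volume) analysis on voxel grids, lattice percolation of the
    accessible space between the two faces of the pore, potentials of mean force
    from void occupancy statistics or from centre-of-mass traces, a discretised
    one-dimensional Smoluchowski (Fokker-Planck) first-passage solver with
    Fick-Jacobs position-dependent diffusivity, and the scaling-law fit that
    locates the soft-to-hard barrier crossover.  A synthetic anchored
    self-avoiding-walk mesh generator with the Lin2016, Kim2018 and Kim2018+
    NPC stoichiometries stands in for long coarse-grained trajectories, so the
    whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
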