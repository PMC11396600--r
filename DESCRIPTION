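Package: msmflux
Title: Markov State Models, Transition-Path Flux Analysis and Trajectory
    Observables for Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the post-simulation analysis chain that links protein
    conformational dynamics to phenotype: structural observables from
    trajectories (RMSD, radius of gyration, RMSF, solvent-accessible surface
    area, dynamical cross-correlation matrices, inter-helix pocket distances,
    alpha-helix content), k-means microstate discretization with VAMP-2
    scoring, Markov state model estimation and Chapman-Kolmogorov validation,
    PCCA+ macrostate coarse-graining, transition-path-theory committors, flux
    and pathway decomposition, and MM/PBSA energy-component aggregation.
    Includes synthetic-data generators (discrete Markov chains, overdamped
    Langevin dynamics on multi-well potentials, correlated Gaussian positional
    ensembles, energy-component tables) so every stage can be exercised
    against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
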