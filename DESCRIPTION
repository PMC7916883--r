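Package: tidytraj
Title: Tidy Comparative Analysis of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for comparative analysis of protein molecular dynamics
    trajectories, built around the workflow used to contrast homologous
    enzymes (for example a cold-adapted enzyme against its mesophilic
    counterpart): least-squares (Kabsch) superposition with self- and
    non-self fitting, RMSD time series and per-residue RMSF profiles with
    region-level statistics, geometric interaction measures (solvent
    accessible surface area, close contacts, hydrogen bonds, radius of
    gyration), essential dynamics (C-alpha covariance analysis) with
    cosine-content sampling diagnostics and porcupine-mode extraction,
    two-dimensional free-energy landscapes by Boltzmann inversion with
    basin enumeration, replicate-level statistics, and seeded synthetic
    trajectory generators with known ground truth for validating every
    stage. Structures and trajectories are read and written as (multi-model)
    PDB text; results are returned as tibbles that compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
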