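Package: mdunfold
Title: Order Parameters, Free-Energy Landscapes and Unfolding Analysis for
    Protein Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of protein thermal-unfolding trajectories stored as
    multi-model PDB files. Computes per-frame structural order parameters
    (C-alpha RMSD by Kabsch superposition, radius of gyration, fraction of
    native contacts, Shrake-Rupley solvent-accessible surface area,
    intraprotein hydrogen-bond counts) and per-residue fluctuations (RMSF),
    builds two-dimensional free-energy landscapes by Boltzmann inversion of
    joint order-parameter histograms with basin detection, computes dynamic
    cross-correlation matrices over trajectory windows, and assigns
    secondary structure per frame with a simplified Kabsch-Sander scheme.
    Includes a synthetic multi-state trajectory generator (Markov-switching
    conformer templates with Gaussian coordinate noise) so every stage of
    the pipeline can be validated against known ground truth without
    running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
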