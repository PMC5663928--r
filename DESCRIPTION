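Package: alchemtraj
Title: Alchemical Free-Energy Estimation and Trajectory Thermodynamics for
    Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for relative ligand-binding
    thermodynamics from molecular dynamics and alchemical free energy
    perturbation (FEP) output. Implements Zwanzig exponential-averaging
    window estimators with block standard errors and bidirectional
    midpoint-outward window combination, thermodynamic-cycle closure
    checks, two-temperature finite-difference decomposition of binding
    free-energy differences into enthalpic and entropic components,
    quasi-harmonic configurational entropy from the eigen-spectrum of the
    mass-weighted coordinate covariance, geometric hydrogen-bond,
    water-bridge and hydrophobic-contact occupancy analysis, least-squares
    (Kabsch) superposition with RMSD/RMSF metrics, and fixed-radius
    k-means conformational clustering of ligand structures. A synthetic
    data module generates trajectories, per-window FEP samples and
    planted protein-ligand-water complexes with analytic ground truth, so
    every stage is testable without a simulation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
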