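Package: bindkin
Title: Binding Free Energies, Inhibition Kinetics and Trajectory Geometry
    for Protein-Ligand Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-point binding-free-energy estimation from molecular-dynamics
    interaction-energy time series using the linear interaction energy (LIE)
    and linear response approximation (LRA) estimators with replicate
    aggregation; steady-state enzyme inhibition kinetics for pure
    non-competitive, linear mixed and partial (hyperbolic) mixed inhibition,
    including the Lineweaver-Burk primary/secondary/tertiary replot chain,
    direct nonlinear global fitting of Ki and Ki', four-parameter logistic
    IC50 dose-response fits and assay-unit helpers; superposition-based
    RMSD/RMSF trajectory analysis with Kabsch alignment and geometric
    protein-ligand interaction profiling (hydrogen bonds, hydrophobic
    contacts, pi-stacking, pi-cation) with per-frame occurrence statistics;
    plus seeded synthetic-data generators with known ground truth for all
    three input classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
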