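Package: ffbalance
Title: Protein-Water Lennard-Jones Balance Tools for CHARMM Force Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates lambda-scaled protein-water Lennard-Jones cross-term
    (NBFIX) tables for CHARMM-dialect force fields and implements the
    analysis battery used to validate such scalings: backbone dihedral and
    helicity statistics (window criterion and a DSSP-style hydrogen-bond
    assignment), Kabsch superposition RMSD/RMSF, free-energy surfaces from
    biased simulations (histogram, Gaussian-accelerated-MD cumulant
    reweighting, MBAR over umbrella windows, and the combined two-step
    scheme), Bennett acceptance ratio solvation free energies with block
    errors, and finite-size-corrected translational diffusion for dilute
    and crowded protein solutions (Yeh-Hummer correction, Einstein
    suspension viscosity, experimental-viscosity rescaling). Includes
    seeded synthetic generators for peptide backbones, Brownian and
    Langevin trajectories, and Crooks-consistent work samples.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
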