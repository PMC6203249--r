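Package: smolrate
Title: Steady-State Smoluchowski Reaction Rates and Off-Center Binding in
    Enzyme Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how weak, off-center ligand binding sites change the
    diffusion-influenced reaction rate of a substrate inside an enzyme lumen.
    Solves the steady-state Smoluchowski (diffusion-reaction) equation with a
    finite-volume scheme on parameterized cylindrical enzyme models and on
    imported molecular surface meshes (OFF/PLY/STL), with a radiation
    (Collins-Kimball) boundary condition on the catalytic surface, and converts
    the integrated boundary flux into a bimolecular rate constant. Includes the
    parameter-scan and site-splitting experiments built on the solver, analysis
    procedures for molecular-dynamics trajectories (side-chain swing angle,
    two-state transition-rate estimation, 3D occupancy maps and visited volume,
    ligand center-of-mass displacement and orientation, pairwise distances and
    contact lifetimes), and seeded synthetic-trajectory generators (two-state
    telegraph side chain, confined random-walk ligand, scheduled contact
    fixtures) used to validate those procedures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
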