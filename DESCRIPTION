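Package: cuprobind
Title: Copper-Site Binding Energetics and Inhibition Kinetics for Lytic
    Polysaccharide Monooxygenases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for small-molecule inhibition of the copper
    active site of lytic polysaccharide monooxygenases (LPMOs). Assembles
    counterpoise-corrected ligand-Cu(II) binding energies and their
    decomposition from tabulated quantum-chemical species energies, reduces
    photometric and turbidimetric assay data to specific and residual
    activities and IC50 values, converts binding free energies to inhibition
    constants (Cheng-Prusoff), analyses copper-site hydration from
    trajectories (radial distribution functions, shell coordination numbers,
    RMSD-cutoff clustering) and Cu(II) coordination geometry (donor
    distances, axial/equatorial roles, denticity, hydrogen-bond contacts),
    and correlates ln(IC50) with binding energies. Includes seeded synthetic
    generators for every data type the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
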