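Package: monofilm
Title: Thermodynamic and Structural Analysis of Lipid Langmuir Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the two standard tracks of lipid-monolayer analysis.
    The thermodynamic track reads surface pressure-area (pi-A) Langmuir
    isotherms and computes the surface compressional modulus Cs^-1 =
    -A (dpi/dA), classifies two-dimensional phase states, detects lift-off,
    LE-LC plateau and collapse features, and evaluates the excess Gibbs free
    energy of mixing of binary films by integrating the excess area per
    molecule over surface pressure, with condensation and complex
    stoichiometry analysis. The structural track computes observables on
    monolayer molecular-dynamics configurations (PDB or extended-XYZ frames
    with orthorhombic boxes): electron density profiles along the interface
    normal, radial distribution functions with running coordination numbers,
    P-N headgroup tilt angles, torsion-angle distributions with conformer
    classification, and area per molecule. Seed-deterministic synthetic-data
    generators with closed-form ground truth stand in for experimental
    isotherms and trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
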