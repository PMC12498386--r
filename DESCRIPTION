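Package: gagdyn
Title: Conformational Analysis of Glycosaminoglycan Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the conformational dynamics of sulfated
    glycosaminoglycan chains such as heparin from molecular dynamics
    ensembles. Classifies pyranose ring puckering (4C1, 1C4, 2SO, 1S3)
    from the gamma/delta ring dihedrals, extracts glycosidic phi/psi
    torsions and locates their population modes on the torus, and computes
    global shape descriptors (RMSD time series and pairwise RMSD matrices
    after optimal superposition, radius of gyration, end-to-end distance,
    inter-residue distance maps) together with their correlations. Includes
    a synthetic ensemble generator that builds idealized pyranose rings at
    prescribed Cremer-Pople coordinates and heparin-like dodecamer chains
    with controllable pucker-state populations and linkage torsion
    distributions, a registry of five explicit water models with pairwise
    interaction energetics, and multi-model PDB/XYZ readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
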