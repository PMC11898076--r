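Package: gradeFP
Title: GRAIL-Based Interaction Fingerprint Descriptors for Protein-Ligand Complexes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes GRADE and X-GRADE, fixed-length floating-point
    interaction-fingerprint descriptors for protein-ligand complexes. The
    35-element GRADE vector and the 177-element X-GRADE vector combine a
    pose-independent block of ligand pharmacophoric feature counts and
    physicochemical properties with a pose-dependent block of GRAIL
    feature-pair interaction scores, binding-site H-bond coverage terms,
    and physics-based energies (unscaled Coulomb electrostatics and a
    Morse-potential van der Waals split parameterized with Universal Force
    Field atom parameters). Includes readers for PDB/mmCIF receptors and
    SDF/MOL2 ligand poses, a synthetic-complex fixture generator, batch
    computation, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    bio3d,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Cheminformatics, StructuralPrediction, FeatureExtraction
RoxygenNote: 7.3.3
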