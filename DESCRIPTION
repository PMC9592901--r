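Package: ffforge
Title: Machine-Learned Force-Field Parameterization for Drug-Like Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates simulation-ready GROMACS topologies for drug-like small
    molecules from trainable models of atomic partial charges, GAFF-style atom
    types, dihedral phase angles and periodicities, and bond/angle force
    constants. Atoms are described by fixed-width descriptors of their first,
    second and third bonded shells; a random-forest head predicts charges and
    feed-forward classifier heads assign categorical parameters. A synthetic
    label oracle (electronegativity-equalization charges plus rule-based GAFF
    atom typing) makes every stage trainable and testable without quantum
    chemistry. Includes a Bennett Acceptance Ratio estimator and alchemical
    lambda-schedule builder for solvation free-energy validation workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
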