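Package: coevfilter
Title: Self-Consistency Filtering of Coevolution-Predicted Residue Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removes false positives from ranked lists of coevolution-predicted
    residue-residue contacts by requiring structural self-consistency. Predicted
    contacts are applied as distance restraints in repeated simulated-annealing
    structure calculations in torsion space, with predicted secondary-structure
    segments held at canonical dihedral angles. Each restraint carries a
    stochastically sampled weight that lets the calculation switch a
    geometrically inconsistent restraint off at an annealed energetic cost;
    contacts switched on in a consensus of independent runs are retained.
    Includes readers and writers for FASTA, PSIPRED, CASP-RR and PDB formats,
    evaluation metrics against reference structures (precision, recall,
    restraint violation energy, Kabsch superposition, GDT), effective-sequence
    counting for alignments, and deterministic synthetic fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
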