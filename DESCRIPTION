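Package: dockface
Title: Scoring Rigid-Body Protein-Protein Docking Decoys with Predicted
    Interface Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rescores rigid-body protein-protein docking poses using
    per-residue interface probabilities. Provides bound/unbound structure
    preparation (chain relabeling, BLOSUM62-based residue mapping,
    trimming, Kabsch superposition), native-interface extraction by
    solvent-accessibility difference, ingestion of interface, contact and
    distogram predictions, simulation of noisy interface predictions at
    controlled recall and precision, an interface-probability scoring
    function for decoy ranking, distance-restraint generation and
    checking, and model quality assessment (DockQ, precision-recall AUC,
    top-N success rates, docking difficulty classes). A synthetic
    toy-complex generator makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
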