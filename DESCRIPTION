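Package: loopflex
Title: Mining, Flexibility Labelling and Classification of Beta-Hairpin Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the conformational flexibility of protein loops
    bounded by two antiparallel beta-strands, including antibody and T-cell
    receptor CDR3 loops. The package mines loop motifs from crystal structures
    (with an internal Kabsch-Sander secondary-structure backend), groups
    sequence-identical loops, clusters their conformations by superposed
    C-alpha RMSD with complete linkage, and labels loops as flexible or rigid.
    A residue-graph neural classifier with E(3)-invariant message passing
    predicts flexibility from a single structure; logistic-regression baselines
    on loop length and solvent exposure, identity-aware data splitting,
    precision-recall and ROC metrics, and a synthetic beta-hairpin generator
    for fully reproducible experiments are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
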