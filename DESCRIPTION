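Package: wafermotif
Title: Dimer-Interface Wafer Motif Analysis for Glutathione Transferase
    Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Structural analysis of the histidine 'wafer' subunit-interface
    motif of Epsilon-class glutathione transferases (GSTs): parsing of PDB
    and mmCIF coordinate files into a uniform atom table, aromatic
    ring-plane and pi-stacking geometry, detection of cross-interface
    stacked histidine pairs with their supporting serines, classification
    of protein-glutathione (GSH) contacts by tripeptide moiety,
    rigid-body Kabsch superposition with whole-structure RMSD between
    homologs, WebLogo-style alignment-column information content mapped
    onto structure numbering, and deterministic synthetic-structure
    generators that plant all of the above for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
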