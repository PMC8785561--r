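Package: complexcons
Title: Conservation Analysis of Multi-Protein Complex Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative conservation analysis of multi-protein
    (and protein-RNA) complexes. Computes per-column Jensen-Shannon
    divergence conservation tracks from multiple sequence alignments
    against a BLOSUM62-derived background, identifies inter-chain
    interface residues in 3-D structures with geometric contact criteria,
    classifies interface residues as core or rim by relative solvent
    accessibility (Shrake-Rupley), builds and clusters phylogenetic
    presence/absence profiles (correlation distance, average linkage),
    scans sequences for proline-rich motifs, and aggregates the results
    into site-level conservation reports. A seeded synthetic-data module
    generates alignments, toy complexes, profiles and motif sequences
    with known ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    bio3d,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
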