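Package: xlbench
Title: Ground-Truth Benchmarking of Crosslinking-MS Search Results with Synthetic Peptide Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking crosslinking mass spectrometry (XL-MS)
    identification workflows against a group-partitioned synthetic crosslinked
    peptide library with known ground truth. Provides in-silico tryptic
    digestion and single-lysine peptide selection, group partitioning and
    enumeration of the admissible crosslink space, monoisotopic mass and
    fragment-ion arithmetic for non-cleavable and MS-cleavable crosslinkers
    (including diagnostic stub doublets), a synthetic spectrum and
    crosslink-spectrum-match (CSM) generator with truth manifests, a minimal
    fully specified crosslink search engine, target-decoy false discovery rate
    (FDR) estimation at the CSM, unique-CSM and peptide-pair levels with
    shuffled or inverted decoy databases, and evaluation of accepted results
    against the library design: calculated (actual) FDR, CSM redundancy, FDR
    propagation from CSM to unique-crosslink level, cross-engine overlap,
    score correlation and MS2 spectra accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
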