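Package: sigtax
Title: Diagnostic Nucleotide Signatures and DNA-Based Taxon Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: DNA-based taxonomy toolkit for annotated rRNA-operon alignments:
    IUPAC-ambiguity-aware mining and verification of diagnostic nucleotide
    signatures (short degenerate motifs unique to a target taxon under an
    allowed-mismatch budget, including OR-disjunctions), barcode-gap analysis
    from intra- and interspecific p-distances, mapping of alignment columns to
    reference-sequence coordinates across SSU/ITS1/5.8S/ITS2/LSU regions,
    monophyly and bootstrap-support checks for taxon delimitation on
    support-annotated trees, threshold clustering for species-richness
    estimation, rendering of formal molecular Diagnoses, and a synthetic
    alignment generator with known truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
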