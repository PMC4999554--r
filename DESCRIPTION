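Package: piptyper
Title: Variable-Region Typing of the Enterococcal Phage Infection Protein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-typing toolkit for the Enterococcus faecalis phage
    infection protein (PIP_EF, locus EF0858). Extracts the hypervariable
    region (reference amino acids 342-494) from full-length PIP genes or
    proteins by anchored global alignment, clusters variable regions into
    clades at a 95 percent nucleotide-identity cutoff, predicts strain
    susceptibility to the lytic phages phiVPE25 and phiVFW from clade
    membership, classifies variable-region amplicon reads to profile clade
    abundance in environmental samples, and calls loss-of-function mutations
    (nonsense, frameshift, insertion-sequence disruption) in the PIP gene of
    phage-resistant isolates. A deterministic simulator generates
    clade-structured genes, error-bearing amplicon reads and mutagenized
    isolates with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
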