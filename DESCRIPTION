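Package: ampliMHC
Title: Replicate-Validated MHC Amplicon Genotyping and Molecular Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of barcoded 454-style amplicon
    sequencing of highly polymorphic immune genes such as MHC class I.
    Generates synthetic allele pools, multi-allele individual genotypes and
    error-bearing barcoded reads with a machine-readable truth set;
    demultiplexes reads by MID barcode with an IUPAC-aware edit distance
    and calls per-individual allele sets with replicate-concordance and
    relative-frequency filters; and computes downstream molecular-evolution
    statistics on the resulting allele alignment: pairwise divergence,
    Nei-Gojobori dN/dS with Jukes-Cantor correction and a Z-test for
    positive selection, per-residue variability, the Hudson-Kaplan minimum
    number of recombination events, a gene-conversion fragment permutation
    scan, a multilocus linkage-disequilibrium randomization test,
    neighbor-joining trees with bootstrap support, and a quadratic
    association between individual allele count and body condition.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    methods,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
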