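Package: nrcfv
Title: Size-Normalized Compositional Heterogeneity Metrics for Sequence
    Alignments
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies compositional heterogeneity in nucleotide and amino
    acid multiple sequence alignments with the RCFV metric family (total,
    character-specific and taxon-specific Relative Composition Frequency
    Variability) and its size-normalized successors nRCFV, ncsRCFV and
    ntsRCFV, which remove the dependence of the raw metrics on sequence
    length, taxon count and alphabet size. Includes FASTA and relaxed
    PHYLIP input/output with explicit missing-data semantics, a seeded
    simulator of compositionally homogeneous alignments for bias studies,
    gapped/ungapped mimic-pair generation for missing-data experiments,
    per-partition gene scoring with quantile (sextile) binning and
    selection comparison for supermatrix curation, and a command-line
    interface with tabular and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
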