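Package: rankmer
Title: Rank-Based k-mer Enrichment Analysis of Activated Chromatin Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize the DNA sequence composition of genomic
    regions that gain histone modifications after treatment with epigenetic
    inhibitors. Implements fold-change calling of differential ChIP-seq
    regions, promoter/enhancer/other classification from H3K4me2 and H3K4me3
    coverage, exhaustive k-mer frequency ranking in fixed windows around peak
    centers, Kolmogorov-Smirnov rank-enrichment tests for IUPAC degenerate
    sequence classes (W/S), nearest-gene expression-shift testing, and a
    synthetic-data generator with planted composition biases so the whole
    pipeline is testable without external data. Also includes a monoisotopic
    mass calculator for molecular-formula ions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
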