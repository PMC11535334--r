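Package: auxseq
Title: Analysis of Barcoded Fragment Libraries in Pooled Auxotroph
    Complementation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled complementation screens in which DNA-barcoded
    genomic fragment libraries are selected in auxotrophic host strains and
    assayed by barcode sequencing (BarSeq). Converts BarSeq reads to
    per-barcode counts with quality filtering and off-by-one barcode
    elimination, computes per-barcode log2 fitness and count-noise z
    statistics for selected versus pre-selection (t0) samples, calls
    high-confidence complementing fragments, merges overlapping hits into
    genomic regions and associates causative genes, and quantifies recovery
    of a-priori expected hits with binomial confidence intervals and
    sequence covariates (GC content, codon adaptation index, rare codons).
    Includes a synthetic-data generator that emulates the statistical
    structure of such screens (sheared fragment libraries, log-normal t0
    abundances with dropout, orientation-dependent selection, background
    colony mass) so that every analysis stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    seqinr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
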