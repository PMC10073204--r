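Package: iesight
Title: IES Retention, Nucleosome Density and Small-RNA Profiling for
    Programmed DNA Elimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for programmed DNA elimination in ciliates.
    Computes per-IES retention scores (IRS) from paired-end alignments against
    MAC and MAC+IES references, DNA-seq-normalized nucleosome densities over
    IESs with mononucleosome size gating, library downsampling and stratified
    two-sample Kolmogorov-Smirnov comparisons, and small-RNA length-class
    profiles partitioned by genomic compartment. A synthetic-data generator
    emulates a Paramecium-like genome pair and all sequencing inputs with known
    ground truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
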