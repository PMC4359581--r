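Package: gbskit
Title: Design and Demultiplexing of Genotyping-by-Sequencing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for restriction-enzyme based reduced representation
    sequencing (genotyping by sequencing, GBS). Provides an in silico
    digest of a reference genome for enzyme evaluation, generation of
    self-correcting variable-length in-line barcodes built on Hamming(15,11)
    codes, barcode- and enzyme-aware demultiplexing and trimming of single-
    and paired-end FASTQ files with a mate-pair consistency correction,
    discovery of unknown in-line barcodes, and a GBS read simulator with
    per-read ground truth for evaluating demultiplexing sensitivity,
    misassignment and trimming accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    tools,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
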