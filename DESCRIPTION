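Package: spermkit
Title: Sperm RNA Element Profiling and Seasonal Differential Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for profiling the highly fragmented transcriptome of
    ejaculated spermatozoa from bulk RNA-seq alignments. Detects sperm RNA
    elements (SREs) as intervals of clustered read coverage, quantifies them
    in RPKM, partitions them into abundance deciles and annotation classes
    (exonic, novel intronic, upstream/downstream 10 kb, orphan), scores
    per-transcript integrity (TIN) from coverage uniformity, classifies
    cross-sample abundance stability by coefficient of variation,
    characterizes repeat-element and long non-coding RNA content, calls de
    novo piRNA clusters from 26-33 nt small-RNA reads, and tests two-season
    designs for differential abundance with a negative-binomial model and
    batch adjustment. Includes a synthetic-data generator with known ground
    truth so every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    MASS,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
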