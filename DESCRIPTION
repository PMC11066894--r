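Package: covdepth
Title: Fast Coverage and Depth Statistics from BAM/CRAM Alignments
Version: 0.1.0
Authors@R: person("covdepth", "maintainers", email = "covdepth@example.org",
    role = c("aut", "cre"))
Description: Computes covered sites, total depth, coverage percentage, mean
    depth and optional GC content from BAM or CRAM alignment files, per
    chromosome, per gene (from GFF3/GTF annotation with merged CDS or exon
    intervals), per BED region, or per fixed-size window.  Depth is
    accumulated from the alignment position and CIGAR string of each read
    into bounded-memory blocked integer arrays, work is partitioned across
    chromosomes for parallel execution, and reads are filtered by SAM FLAG
    bits and mapping quality.  Includes a synthetic alignment fixture
    generator with a naive per-base pileup oracle for exact equivalence
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: samtools (for CRAM decoding and fixture generation)
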