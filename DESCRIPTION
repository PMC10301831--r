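Package: deepdel
Title: Deletion Detection and Genotyping from Long-Read Alignments with a
    Convolutional Attention Recurrent Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and genotypes genomic deletions (50 bp - 10 kb) from
    coordinate-sorted long-read alignments, optionally combined with short
    paired-end reads. Reference tiles of 200 bp are summarised into nine-row
    alignment-signature matrices (coverage, CIGAR deletion ops, clip and
    split-read boundaries, block mean depth); a convolutional network with a
    convolutional block attention module (CBAM) and a bidirectional GRU
    classifies tiles, a deterministic heuristic refines CIGAR and split-read
    sub-signatures into base-exact breakpoints, and a companion CNN assigns
    heterozygous or homozygous genotypes by majority vote. Includes a diploid
    alignment simulator for training and validation at desk scale, VCF output
    and a truth-matching evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
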