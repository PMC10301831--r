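aln_row <- function(read_id = "r1", strand = "+", ref_start = 0L,
                    ref_end = 100L, read_start = 0L, read_end = 100L,
                    cigar = "100M", n_segments = 1L) {
  data.frame(read_id = read_id, strand = strand, ref_start = ref_start,
             ref_end = ref_end, read_start = read_start,
             read_end = read_end, cigar = cigar, n_segments = n_segments)
}

test_that("CIGAR deletion signatures follow the >30 bp / <200 bp rule", {
  a <- aln_row(ref_start = 100L, ref_end = 240L, cigar = "50M40D50M")
  s <- cigar_deletion_signatures(a, "chr1", 0L, 200L)
  expect_equal(s$rref_start, 150L)
  expect_equal(s$rref_end, 190L)
  # 25 bp D is at the threshold's wrong side (strict > 30)
  b <- aln_row(ref_start = 100L, ref_end = 325L, cigar = "100M25D100M")
  expect_equal(nrow(cigar_deletion_signatures(b, "chr1", 0L, 200L)), 0L)
  # a 31 bp D passes
  c31 <- aln_row(ref_start = 100L, ref_end = 231L, cigar = "50M31D50M")
  expect_equal(nrow(cigar_deletion_signatures(c31, "chr1", 0L, 200L)), 1L)
  # D starting >= 200 bp from the region start is not attributed to it
  far <- aln_row(ref_start = 250L, ref_end = 390L, cigar = "50M40D50M")
  expect_equal(nrow(cigar_deletion_signatures(far, "chr1", 0L, 200L)), 0L)
})

test_that("same-read signatures closer than 20 bp merge", {
  a <- aln_row(ref_start = 100L, ref_end = 310L,
               cigar = "50M40D15M55D50M")   # D at [150,190) and [205,260)
  s <- cigar_deletion_signatures(a, "chr1", 100L, 300L)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$rref_start, s$rref_end), c(150L, 260L))
  # gap of exactly 20 bp stays separate
  b <- aln_row(ref_start = 100L, ref_end = 315L,
               cigar = "50M40D20M55D50M")
  expect_equal(nrow(cigar_deletion_signatures(b, "chr1", 100L, 300L)), 2L)
})

test_that("split segments recover read coordinates from clips", {
  bam <- make_bam(data.frame(
    qname = c("r1", "r1"), flag = c(0L, 2048L), pos = c(1001L, 2001L),
    cigar = c("500M1500S", "500H400M")), chrom_length = 4000L)
  aln <- alignment_table(bam, "chr1", 4000L)
  segs <- split_segments(aln)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$ref_start, c(1000L, 2000L))
  expect_equal(segs$ref_end, c(1500L, 2400L))
  expect_equal(segs$read_start, c(0L, 500L))
  expect_equal(segs$read_end, c(500L, 900L))
  # single unclipped record: one segment spanning the whole read
  bam2 <- make_bam(data.frame(qname = "r2", flag = 0L, pos = 11L,
                              cigar = "300M"), chrom_length = 4000L)
  a2 <- alignment_table(bam2, "chr1", 4000L)
  expect_equal(c(a2$read_start, a2$read_end), c(0L, 300L))
})

test_that("reverse-strand records pair in the reference-oriented frame", {
  # minus-strand split pair: SAM clips are reference-ordered, so the
  # reference-oriented query coordinates come from the leading clips;
  # flipping the as-sequenced coordinates gives the same frame
  bam <- make_bam(data.frame(
    qname = c("r1", "r1"), flag = c(16L, 2064L), pos = c(1001L, 2001L),
    cigar = c("500M1500S", "500H400M1100H")), chrom_length = 4000L)
  segs <- split_segments(alignment_table(bam, "chr1", 4000L))
  expect_equal(segs$read_start, c(0L, 500L))
  expect_equal(segs$read_end, c(500L, 900L))
  # as-sequenced coordinates are [1500,2000) and [1100,1500); flipping by
  # the read length (2000) reproduces the frame used above
  expect_equal(2000L - c(2000L, 1500L), c(0L, 500L))
  r <- split_distance(segs[1, ], segs[2, ], "chr1")
  expect_equal(r$distance, 500L)                 # (2000-1500)-(500-500)
  expect_equal(c(r$signature$rref_start, r$signature$rref_end),
               c(1500L, 2000L))
})

test_that("split distance implements the reference/read gap difference", {
  s1 <- aln_row("r1", "+", 1000L, 1500L, 0L, 500L)
  s2 <- aln_row("r1", "+", 2000L, 2400L, 510L, 910L)
  r <- split_distance(s1, s2, "chr1")
  expect_equal(r$distance, 490L)
  expect_equal(c(r$signature$rref_start, r$signature$rref_end),
               c(1500L, 1990L))
  # perfectly contiguous segments: distance 0, no signature
  s3 <- aln_row("r1", "+", 1500L, 1700L, 500L, 700L)
  r0 <- split_distance(s1, s3, "chr1")
  expect_equal(r0$distance, 0L)
  expect_null(r0$signature)
  # exactly 40 bp: strict threshold, no signature
  s4 <- aln_row("r1", "+", 1540L, 1700L, 500L, 660L)
  r40 <- split_distance(s1, s4, "chr1")
  expect_equal(r40$distance, 40L)
  expect_null(r40$signature)
  # precondition failures are silent no-signatures
  expect_true(is.na(split_distance(aln_row("r1"), aln_row("r2"))$distance))
  sneg <- aln_row("r1", "-", 2000L, 2400L, 510L, 910L)
  expect_true(is.na(split_distance(s1, sneg)$distance))
})

test_that("clustering follows the 1500 bp chained rule", {
  s <- data.frame(chrom = "chr1", rref_start = c(1000L, 1400L),
                  rref_end = c(1490L, 1900L), source = "cigar",
                  read_id = c("a", "b"))
  expect_equal(unique(cluster_signatures(s)$bin), 1L)
  s2 <- s; s2$chrom <- c("chr1", "chr2")
  expect_equal(length(unique(cluster_signatures(s2)$bin)), 2L)
  s3 <- data.frame(chrom = "chr1", rref_start = c(1000L, 2600L),
                   rref_end = c(1490L, 3100L), source = "cigar",
                   read_id = c("a", "b"))
  expect_equal(length(unique(cluster_signatures(s3)$bin)), 2L)
  # boundary: 1500 joins, 1501 does not
  b <- data.frame(chrom = "chr1", rref_start = c(1000L, 2500L),
                  rref_end = c(1500L, 3000L), source = "cigar",
                  read_id = c("a", "b"))
  expect_equal(length(unique(cluster_signatures(b)$bin)), 1L)
  b$rref_start[2] <- 2501L; b$rref_end[2] <- 3001L
  expect_equal(length(unique(cluster_signatures(b)$bin)), 2L)
})

test_that("bins summarise to lower-median start and median length", {
  b <- data.frame(chrom = "chr1", rref_start = c(1000L, 1004L, 1010L),
                  rref_end = c(1000L, 1004L, 1010L) + c(490L, 498L, 500L),
                  source = "cigar", read_id = c("a", "b", "c"))
  call <- finalize_call(b, min_support = 1L)
  expect_equal(c(call$start, call$end, call$support), c(1004L, 1502L, 3L))
  expect_null(finalize_call(b[1, ], min_support = 2L))
  small <- b
  small$rref_end <- small$rref_start + c(45L, 48L, 49L)
  expect_null(finalize_call(small, min_support = 1L))  # median 48 < 50
  # a read contributing two signatures counts once
  dup <- rbind(b, transform(b[1, ], rref_start = 1002L, rref_end = 1490L))
  expect_equal(finalize_call(dup, 1L)$support, 3L)
})

test_that("clustering matches transitive-closure brute force; duplication
           changes support only", {
  set.seed(77)
  for (rep in 1:25) {
    s <- random_signatures(sample(2:4, 1L), 5L)
    got <- cluster_signatures(s)
    key <- paste(got$chrom, got$rref_start, got$rref_end, got$read_id)
    comp <- oracle_cluster(got)
    expect_equal(partition_sets(got$bin), partition_sets(comp))
    # duplicating a signature must not alter the partition of the others
    d <- rbind(s, s[sample(nrow(s), 1L), ])
    gd <- cluster_signatures(d)
    kd <- paste(gd$chrom, gd$rref_start, gd$rref_end, gd$read_id)
    m <- match(key, kd)
    expect_equal(length(unique(gd$bin[m])), length(unique(got$bin)))
  }
})

test_that("noise-free planted deletions are recovered base-exactly", {
  spec <- simulation_spec(ref_length = 150000L, n_deletions = 4L,
                          size_range = c(80L, 2500L), het_fraction = 0,
                          long_coverage = 25, short_coverage = 0,
                          long_read_mean_len = 5000L, d_op_max = 1000L,
                          base_error_rate = 0, seed = 13L)
  ds <- simulate_dataset(spec, tempfile("bp_"))
  aln <- alignment_table(ds$long_bam, "chrS", spec$ref_length)
  grid <- tile_reference(spec$ref_length, 200L)
  flagged <- grid[label_tiles(grid, ds$truth) == 1L, ]
  calls <- refine_breakpoints(aln, flagged, "chrS", min_support = 3L)
  expect_equal(nrow(calls), nrow(ds$truth))
  expect_equal(calls$start, ds$truth$start)
  expect_equal(calls$end, ds$truth$end)
})
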