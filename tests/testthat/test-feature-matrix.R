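test_that("reference tiling is consecutive, non-overlapping and covering", {
  expect_equal(tile_reference(450, 200, 0),
               data.frame(start = c(0L, 200L, 400L),
                          end = c(200L, 400L, 450L)))
  expect_equal(tile_reference(700, 200, 100),
               data.frame(start = c(100L, 300L, 500L),
                          end = c(300L, 500L, 700L)))
  expect_equal(tile_reference(200, 200, 0),
               data.frame(start = 0L, end = 200L))
  expect_error(tile_reference(0, 200), "positive")
  for (i in 1:20) {
    len <- sample(300:5000, 1L); L <- sample(c(100L, 200L, 333L), 1L)
    off <- sample.int(L, 1L) - 1L
    g <- tile_reference(len, L, off)
    expect_true(all(g$end > g$start))
    expect_true(all(g$end - g$start <= L))
    expect_equal(g$start[-1], g$end[-nrow(g)])   # consecutive
    expect_equal(g$start[1], off)
    expect_equal(g$end[nrow(g)], len)
  }
})

test_that("block mean coverage equals per-base depth sum over block length", {
  empty <- make_bam(data.frame(qname = "r1", flag = 0L, pos = 1L,
                               cigar = "50M", mapq = 5L),
                    chrom_length = 1000L)
  expect_equal(unname(block_mean_coverage(empty, "chr1", 1000L, 1000L)), 0)

  one <- make_bam(data.frame(qname = "r1", flag = 0L, pos = 101L,
                             cigar = "100M"), chrom_length = 1000L)
  expect_equal(unname(block_mean_coverage(one, "chr1", 1000L, 1000L)), 0.1)

  two <- make_bam(data.frame(qname = c("r1", "r2"), flag = 0L,
                             pos = 101L, cigar = "100M"),
                  chrom_length = 1000L)
  expect_equal(unname(block_mean_coverage(two, "chr1", 1000L, 1000L)), 0.2)
})

test_that("position signatures match a CIGAR-walk on a deletion read", {
  # one long read at 0-based pos 100 with a 40 bp deletion
  bam <- make_bam(data.frame(qname = "r1", flag = 0L, pos = 101L,
                             cigar = "50M40D50M"), chrom_length = 400L)
  sig <- extract_position_signatures(bam, NULL, "chr1", 0L, 400L,
                                     chrom_length = 400L)
  expect_equal(sig$read_ld, as.numeric(seq(0, 399) %in% 150:189))
  expect_equal(sig$read_lc, as.numeric(seq(0, 399) %in% 100:239))
  expect_true(all(sig$read_ld <= sig$read_lc))
})

test_that("clip boundaries are recorded on the aligned side", {
  # right part aligned at 0-based 300, left part soft-clipped
  bam <- make_bam(data.frame(qname = "r1", flag = 0L, pos = 301L,
                             cigar = "100S100M"), chrom_length = 600L)
  sig <- extract_position_signatures(bam, NULL, "chr1", 0L, 600L)
  expect_equal(which(sig$read_lrb == 1) - 1L, 300L)
  expect_equal(sum(sig$read_llb), 0)
})

test_that("signature extraction agrees exactly with brute force", {
  set.seed(41)
  for (rep in 1:6) {
    recs_l <- random_records(sample(8:25, 1L))
    recs_s <- random_records(sample(5:15, 1L))
    bam_l <- make_bam(recs_l)
    bam_s <- make_bam(recs_s)
    got <- signature_tracks(bam_l, bam_s, "chr1", 2000L)$counts
    want <- oracle_tracks(recs_l, recs_s, 2000L)
    expect_equal(unname(got), unname(want))
  }
})

test_that("absent chromosome yields zero signatures with a warning", {
  bam <- make_bam(data.frame(qname = "r1", flag = 0L, pos = 1L,
                             cigar = "50M"))
  expect_warning(sig <- extract_position_signatures(bam, NULL, "chrMissing",
                                                    0L, 100L),
                 "absent")
  expect_true(all(as.matrix(sig[, -1]) == 0))
})

test_that("signature normalization centres and scales each group", {
  v <- normalize_signature(c(20, 18, 0, 0, 0, 21, 0, 0, 0))
  expect_equal(v[1], (20 - mean(c(20, 18, 0, 0, 0, 21))) /
                 sqrt(mean((c(20, 18, 0, 0, 0, 21) -
                              mean(c(20, 18, 0, 0, 0, 21)))^2)))
  expect_equal(v[1], 1.0297, tolerance = 1e-4)
  expect_equal(v[7:9], c(0, 0, 0))               # zero-variance short group
  expect_equal(normalize_signature(rep(7, 9)), rep(0, 9))
})

test_that("feature matrices are normalized per position, padded, finite", {
  set.seed(42)
  recs <- random_records(30L)
  bam <- make_bam(recs)
  tr <- signature_tracks(bam, NULL, "chr1", 2000L)
  fm <- build_feature_matrix(tr, 1900L, 2000L, L = 200L)
  expect_equal(dim(fm$values), c(9L, 200L))
  expect_true(all(fm$values[, 101:200] == 0))    # zero padding
  expect_equal(fm$pad_mask, seq_len(200) > 100)
  expect_true(all(is.finite(fm$values)))

  x <- featurize_regions(tr, tile_reference(2000L, 200L), 200L)
  raw <- featurize_regions(tr, tile_reference(2000L, 200L), 200L,
                           normalize = FALSE)
  for (i in seq_len(dim(x)[3])) for (j in seq_len(200L)) {
    g <- raw[1:6, j, i]
    if (stats::sd(g) > 0) {
      expect_equal(mean(x[1:6, j, i]), 0, tolerance = 1e-9)
      expect_equal(mean(x[1:6, j, i]^2), 1, tolerance = 1e-9)
    } else {
      expect_equal(x[1:6, j, i], rep(0, 6))
    }
  }
})

test_that("HiFi-only mode zeroes the short-read rows", {
  recs <- random_records(10L)
  bam <- make_bam(recs)
  tr <- signature_tracks(bam, NULL, "chr1", 2000L,
                         deepdel_config(hifi_mode = TRUE))
  x <- featurize_regions(tr, tile_reference(2000L, 200L), 200L)
  expect_true(all(x[7:9, , ] == 0))
})

test_that("doubling alignment depth doubles every raw count", {
  set.seed(43)
  recs <- random_records(15L)
  recs2 <- recs
  recs2$qname <- paste0(recs2$qname, "_dup")
  both <- rbind(recs, recs2)
  t1 <- signature_tracks(make_bam(recs), NULL, "chr1", 2000L)$counts
  t2 <- signature_tracks(make_bam(both), NULL, "chr1", 2000L)$counts
  expect_equal(t2, 2 * t1)
})

test_that("read_ld never exceeds read_lc on simulated data", {
  spec <- simulation_spec(ref_length = 60000L, n_deletions = 3L,
                          size_range = c(60L, 800L), long_coverage = 15,
                          short_coverage = 0, long_read_mean_len = 3000L,
                          base_error_rate = 0.02, seed = 2L)
  ds <- simulate_dataset(spec, tempfile("ld_"))
  tr <- signature_tracks(ds$long_bam, NULL, "chrS", spec$ref_length)
  expect_true(all(tr$counts["read_ld", ] <= tr$counts["read_lc", ]))
})

test_that("feature sets round-trip through the on-disk container", {
  x <- array(rnorm(9 * 50 * 4), c(9, 50, 4))
  meta <- data.frame(chrom = "chr1", start = c(0, 50, 100, 150),
                     end = c(50, 100, 150, 200), label = c(0L, 1L, 0L, 1L))
  p <- tempfile()
  write_feature_set(x, meta, p)
  back <- read_feature_set(p)
  expect_equal(back$x, x)
  expect_equal(back$meta$start, meta$start)
  expect_equal(back$meta$label, meta$label)
})
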