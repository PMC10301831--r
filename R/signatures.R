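## Alignment-signature extraction: nine per-position counts summarising the
## evidence a deletion leaves in a sorted BAM. Rows (in order):
##   1 read_lc  long-read coverage (reference span, D ops count as covered)
##   2 read_ld  long reads whose CIGAR marks the position as deleted (D op)
##   3 read_llb long reads clipped with the aligned part on the left
##             (counted at the last aligned base)
##   4 read_lrb long reads clipped with the aligned part on the right
##             (counted at the first aligned base)
##   5 read_lsp segment boundaries of split (multi-record) long reads
##   6 read_lm  mean long-read coverage of the enclosing block
##   7 read_sc  short-read coverage
##   8 read_slb short-read left-aligned clip boundaries
##   9 read_srb short-read right-aligned clip boundaries
## All coordinates are 0-based, half-open internally.

SIG_ROWS <- c("read_lc", "read_ld", "read_llb", "read_lrb", "read_lsp",
              "read_lm", "read_sc", "read_slb", "read_srb")

.read_alignments <- function(bam, chrom, chrom_length, min_mapq) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE),
    mapqFilter = min_mapq,
    what = c("qname", "flag"),
    which = GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(1L, chrom_length)))
  GenomicAlignments::readGAlignments(bam, param = param)
}

## first/last CIGAR op and length per record, vectorised
.edge_ops <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  n <- lengths(ops)
  u_ops <- unlist(ops, use.names = FALSE)
  u_len <- unlist(lens, use.names = FALSE)
  last <- cumsum(n)
  first <- last - n + 1L
  list(first_op = u_ops[first], first_len = u_len[first],
       last_op = u_ops[last], last_len = u_len[last])
}

.count_vector <- function(pos0, chrom_length) {
  ## pos0: 0-based positions; returns integer vector of per-position counts
  v <- numeric(chrom_length)
  if (length(pos0)) {
    pos0 <- pos0[pos0 >= 0 & pos0 < chrom_length]
    t <- tabulate(pos0 + 1L, nbins = chrom_length)
    v <- as.numeric(t)
  }
  v
}

## per-position track set for one BAM (one read class)
.class_tracks <- function(bam, chrom, chrom_length, config, long = TRUE) {
  gal <- tryCatch(.read_alignments(bam, chrom, chrom_length, config$min_mapq),
                  error = function(e) stop("failed to read ", bam, ": ",
                                           conditionMessage(e)))
  if (length(gal) == 0L) {
    z <- numeric(chrom_length)
    return(list(cov = z, del = z, lb = z, rb = z, sp = z))
  }
  start1 <- GenomicAlignments::start(gal)            # 1-based
  end1 <- GenomicAlignments::end(gal)                # 1-based inclusive
  cig <- GenomicAlignments::cigar(gal)

  ## coverage over the full reference span (D-consumed bases count as
  ## covered so that the deletion fraction del/cov stays in [0,1])
  span <- IRanges::IRanges(start1, end1)
  cov <- as.numeric(IRanges::coverage(span, width = chrom_length))

  ## D-op coverage
  drng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = start1, ops = "D")
  drng_flat <- unlist(drng, use.names = FALSE)
  del <- if (length(drng_flat))
    as.numeric(IRanges::coverage(drng_flat, width = chrom_length))
  else numeric(chrom_length)

  ## clip boundaries
  eo <- .edge_ops(cig)
  has_left_clip <- eo$first_op %in% c("S", "H") & eo$first_len >= config$min_clip
  has_right_clip <- eo$last_op %in% c("S", "H") & eo$last_len >= config$min_clip
  ## aligned part on the LEFT, clip on the right of the span -> last aligned base
  lb <- .count_vector(end1[has_right_clip] - 1L, chrom_length)
  ## aligned part on the RIGHT, clip on the left -> first aligned base
  rb <- .count_vector(start1[has_left_clip] - 1L, chrom_length)

  ## split-alignment boundaries: reads with >= 2 kept records
  sp <- numeric(chrom_length)
  if (long) {
    qn <- S4Vectors::mcols(gal)$qname
    multi <- qn %in% names(which(table(qn) >= 2L))
    if (any(multi)) {
      b <- c(start1[multi] - 1L, end1[multi] - 1L)
      sp <- .count_vector(b, chrom_length)
    }
  }
  list(cov = cov, del = del, lb = lb, rb = rb, sp = sp)
}

#' Mean long-read coverage per genome block
#'
#' Splits a chromosome into fixed-width blocks (default 10 Mbp) and reports
#' the mean long-read depth of each block. The value is used as the
#' `read_lm` feature: every position inside a block shares the block mean,
#' giving the network a local baseline against which coverage drops stand
#' out.
#'
#' @param bam Path to a sorted, indexed BAM of long reads.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param block_size Block width in bp.
#' @param config A [deepdel_config()].
#' @return Numeric vector of block means, one per block, named by 0-based
#'   block start.
#' @export
block_mean_coverage <- function(bam, chrom, chrom_length,
                                block_size = 10000000L,
                                config = deepdel_config()) {
  gal <- .read_alignments(bam, chrom, chrom_length, config$min_mapq)
  span <- IRanges::IRanges(GenomicAlignments::start(gal),
                           GenomicAlignments::end(gal))
  cov <- IRanges::coverage(span, width = chrom_length)
  .block_means_from_cov(as.numeric(cov), chrom_length, block_size)
}

.block_means_from_cov <- function(cov, chrom_length, block_size) {
  starts <- seq.int(0L, chrom_length - 1L, by = block_size)
  ends <- pmin(starts + block_size, chrom_length)
  m <- vapply(seq_along(starts), function(i) {
    sum(cov[(starts[i] + 1L):ends[i]]) / (ends[i] - starts[i])
  }, numeric(1))
  names(m) <- starts
  m
}

.expand_block_means <- function(block_means, chrom_length, block_size) {
  idx <- pmin(length(block_means),
              (seq_len(chrom_length) - 1L) %/% block_size + 1L)
  unname(block_means[idx])
}

#' Whole-chromosome signature tracks
#'
#' Computes the nine per-position alignment-signature tracks for one
#' chromosome in a single pass over the BAM(s). The returned object is the
#' cached input for [build_feature_matrix()], [featurize_regions()] and the
#' calling pipeline, so the BAM is only scanned once per chromosome.
#'
#' @param long_bam Path to the sorted, indexed long-read BAM.
#' @param short_bam Path to the short-read BAM, or `NULL` for HiFi-only
#'   mode (short-read rows stay zero).
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param config A [deepdel_config()].
#' @return An object of class `signature_tracks`: a 9 x `chrom_length`
#'   matrix of raw counts plus metadata.
#' @export
signature_tracks <- function(long_bam, short_bam = NULL, chrom, chrom_length,
                             config = deepdel_config()) {
  chrom_length <- as.integer(chrom_length)
  stopifnot(chrom_length > 0)
  lt <- .class_tracks(long_bam, chrom, chrom_length, config, long = TRUE)
  lm <- .expand_block_means(
    .block_means_from_cov(lt$cov, chrom_length, config$block_size),
    chrom_length, config$block_size)
  if (!is.null(short_bam) && !config$hifi_mode) {
    st <- .class_tracks(short_bam, chrom, chrom_length, config, long = FALSE)
  } else {
    z <- numeric(chrom_length)
    st <- list(cov = z, lb = z, rb = z)
  }
  m <- rbind(lt$cov, lt$del, lt$lb, lt$rb, lt$sp, lm, st$cov, st$lb, st$rb)
  rownames(m) <- SIG_ROWS
  structure(list(chrom = chrom, chrom_length = chrom_length, counts = m,
                 config = config),
            class = "signature_tracks")
}

#' Per-position signature 9-tuples for one sub-region
#'
#' Raw (un-normalized) signature counts for every position of a sub-region.
#' If the chromosome is absent from the alignment file the signatures are
#' all zero and a warning is emitted.
#'
#' @param long_bam,short_bam BAM paths (`short_bam` may be `NULL`).
#' @param chrom Chromosome name.
#' @param start,end Sub-region, 0-based half-open.
#' @param chrom_length Chromosome length; defaults to `end`.
#' @param config A [deepdel_config()].
#' @return Data frame with one row per position (column `pos`, 0-based) and
#'   the nine signature columns.
#' @export
extract_position_signatures <- function(long_bam, short_bam = NULL, chrom,
                                        start, end, chrom_length = end,
                                        config = deepdel_config()) {
  stopifnot(start >= 0, start < end)
  known <- Rsamtools::scanBamHeader(long_bam)[[1]]$targets
  if (!chrom %in% names(known)) {
    warning("chromosome ", chrom, " absent from ", long_bam,
            "; returning zero signatures")
    out <- matrix(0, nrow = end - start, ncol = 9L,
                  dimnames = list(NULL, SIG_ROWS))
    return(cbind(data.frame(pos = seq.int(start, end - 1L)),
                 as.data.frame(out)))
  }
  tr <- signature_tracks(long_bam, short_bam, chrom, chrom_length, config)
  sl <- t(tr$counts[, (start + 1L):end, drop = FALSE])
  cbind(data.frame(pos = seq.int(start, end - 1L)), as.data.frame(sl))
}

#' Normalize one 9-element signature
#'
#' Centers and scales the six long-read elements by their own mean and
#' population standard deviation, and the three short-read elements as a
#' separate group. A group with zero standard deviation maps to zeros (the
#' no-information encoding, consistent with zero padding).
#'
#' @param sig Numeric vector of 9 non-negative finite values, ordered as
#'   `read_lc, read_ld, read_llb, read_lrb, read_lsp, read_lm, read_sc,
#'   read_slb, read_srb`.
#' @return Numeric vector of 9 normalized values.
#' @export
normalize_signature <- function(sig) {
  stopifnot(length(sig) == 9L, all(is.finite(sig)), all(sig >= 0))
  out <- numeric(9L)
  for (idx in list(1:6, 7:9)) {
    g <- sig[idx]
    m <- mean(g)
    s <- sqrt(mean((g - m)^2))
    if (s > 0) out[idx] <- (g - m) / s
  }
  out
}

## group z-score across an array x of dim (9, L, N); returns same shape
.normalize_array <- function(x) {
  d <- dim(x)
  out <- array(0, d)
  for (idx in list(1:6, 7:9)) {
    g <- x[idx, , , drop = FALSE]
    k <- length(idx)
    m <- colMeans(g)                      # (L, N)
    v <- colMeans(g^2) - m^2
    v[v < 0] <- 0
    s <- sqrt(v)
    mrep <- aperm(array(m, c(d[2], d[3], k)), c(3, 1, 2))
    srep <- aperm(array(s, c(d[2], d[3], k)), c(3, 1, 2))
    z <- (g - mrep) / srep
    z[srep == 0] <- 0
    out[idx, , ] <- z
  }
  out
}

#' Feature matrices for a set of sub-regions
#'
#' Slices cached [signature_tracks()] into per-tile 9 x `L` matrices and
#' applies the per-position group normalization. Tiles shorter than `L`
#' (chromosome tail) are zero-padded on the right.
#'
#' @param tracks A `signature_tracks` object.
#' @param regions Data frame with `start`, `end` (0-based half-open), e.g.
#'   from [tile_reference()].
#' @param L Matrix width; defaults to the config used to build `tracks`.
#' @param normalize Apply the group z-score (default) or return raw counts.
#' @return Array of dim `(9, L, nrow(regions))`.
#' @export
featurize_regions <- function(tracks, regions, L = tracks$config$L,
                              normalize = TRUE) {
  stopifnot(inherits(tracks, "signature_tracks"))
  n <- nrow(regions)
  x <- array(0, c(9L, L, n))
  cm <- tracks$counts
  for (i in seq_len(n)) {
    s <- regions$start[i]; e <- regions$end[i]
    w <- min(e, tracks$chrom_length) - s
    if (w > 0) x[, seq_len(w), i] <- cm[, (s + 1L):(s + w)]
  }
  if (normalize) x <- .normalize_array(x)
  x
}

#' Build one normalized feature matrix
#'
#' @param tracks A `signature_tracks` object.
#' @param start,end Sub-region, 0-based half-open; `end - start <= L`.
#' @param L Matrix width.
#' @return List with `values` (9 x L matrix), `pad_mask` (logical length L,
#'   `TRUE` for zero-padded trailing columns) and the sub-region
#'   coordinates.
#' @export
build_feature_matrix <- function(tracks, start, end, L = tracks$config$L) {
  stopifnot(end - start <= L)
  x <- featurize_regions(tracks, data.frame(start = start, end = end), L)
  w <- min(end, tracks$chrom_length) - start
  list(chrom = tracks$chrom, start = start, end = end, L = L,
       values = matrix(x, 9L, L, dimnames = list(SIG_ROWS, NULL)),
       pad_mask = seq_len(L) > w)
}
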