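## Deterministic breakpoint refinement. Network-flagged tiles are turned
## into exact deletion calls from two evidence classes:
##   * intra-read: CIGAR D ops longer than 30 bp starting within 200 bp of
##     the flagged tile's start (merged per read when < 20 bp apart);
##   * inter-read: split alignments -- for two reference-adjacent segments
##     of the same read on the same strand,
##     Distance = (ref2_start - ref1_end) - (read2_start - read1_end),
##     a deletion when Distance > 40 bp.
## Signatures are clustered by a 1500 bp single-linkage rule over the
## sorted stream and each bin is summarised by the lower-median start and
## median length. Calls need >= min_support distinct reads and length >= 50.

## lower median: for even n the smaller of the two central values
.lower_median <- function(x) sort(x)[(length(x) + 1L) %/% 2L]

#' Read an alignment table for breakpoint analysis
#'
#' One row per kept record (primary and supplementary; unmapped, secondary
#' and duplicate records and records under the mapping-quality threshold
#' are dropped), with reference coordinates (0-based half-open) and query
#' coordinates recovered from the clip lengths (hard clips count exactly
#' like soft clips). Query coordinates are expressed in the reference
#' orientation of the read -- the leading SAM clips for either strand --
#' which for reverse-strand records equals flipping the as-sequenced
#' coordinates; in this frame the segments of a split read are collinear
#' with the reference, as the split-distance formula requires.
#'
#' @param bam Sorted, indexed BAM path.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param config A [deepdel_config()].
#' @return Data frame: `read_id`, `strand`, `ref_start`, `ref_end`,
#'   `read_start`, `read_end`, `cigar`, `n_segments`.
#' @export
alignment_table <- function(bam, chrom, chrom_length,
                            config = deepdel_config()) {
  gal <- .read_alignments(bam, chrom, chrom_length, config$min_mapq)
  if (length(gal) == 0L)
    return(data.frame(read_id = character(0), strand = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      read_start = integer(0), read_end = integer(0),
                      cigar = character(0), n_segments = integer(0)))
  cig <- GenomicAlignments::cigar(gal)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  lead <- mapply(function(o, l) sum(l[cumprod(o %in% c("S", "H")) > 0]),
                 ops, lens)
  qcons <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, after.soft.clipping = TRUE)
  strand <- as.character(GenomicAlignments::strand(gal))
  read_start <- lead
  qn <- S4Vectors::mcols(gal)$qname
  data.frame(read_id = qn, strand = strand,
             ref_start = GenomicAlignments::start(gal) - 1L,
             ref_end = GenomicAlignments::end(gal),
             read_start = as.integer(read_start),
             read_end = as.integer(read_start + qcons),
             cigar = cig,
             n_segments = as.integer(ave(seq_along(qn), qn, FUN = length)))
}

.empty_signatures <- function() {
  data.frame(chrom = character(0), rref_start = integer(0),
             rref_end = integer(0), source = character(0),
             read_id = character(0))
}

#' CIGAR deletion sub-signatures within a flagged sub-region
#'
#' Finds D ops longer than 30 bp whose reference start lies within 200 bp
#' of the sub-region start, then merges signatures of the same read that
#' are less than 20 bp apart into one region.
#'
#' @param aln Alignment table (rows overlapping the sub-region are used).
#' @param chrom Chromosome name.
#' @param region_start Flagged sub-region start (0-based).
#' @param region_end Flagged sub-region end.
#' @param min_d_len D length threshold (strict `>`), default 30 bp.
#' @param max_start_dist Maximum `|D start - region start|`, default 200.
#' @param merge_gap Merge same-read signatures closer than this, default 20.
#' @return Data frame of sub-signatures (`chrom`, `rref_start`,
#'   `rref_end`, `source = "cigar"`, `read_id`).
#' @export
cigar_deletion_signatures <- function(aln, chrom, region_start, region_end,
                                      min_d_len = 30L, max_start_dist = 200L,
                                      merge_gap = 20L) {
  ov <- aln[aln$ref_start < region_end & aln$ref_end > region_start, ,
            drop = FALSE]
  if (nrow(ov) == 0L) return(.empty_signatures())
  dr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    ov$cigar, pos = ov$ref_start + 1L, ops = "D")
  n_per <- lengths(dr)
  fl <- unlist(dr, use.names = FALSE)
  if (length(fl) == 0L) return(.empty_signatures())
  sig <- data.frame(rref_start = IRanges::start(fl) - 1L,
                    rref_end = IRanges::end(fl),
                    read_id = rep(ov$read_id, n_per))
  sig <- sig[sig$rref_end - sig$rref_start > min_d_len &
               abs(sig$rref_start - region_start) < max_start_dist, ,
             drop = FALSE]
  if (nrow(sig) == 0L) return(.empty_signatures())
  ## merge close signatures per read
  out <- list()
  for (rid in unique(sig$read_id)) {
    s <- sig[sig$read_id == rid, , drop = FALSE]
    s <- s[order(s$rref_start), , drop = FALSE]
    cs <- s$rref_start[1]; ce <- s$rref_end[1]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$rref_start[i] - ce < merge_gap) {
        ce <- max(ce, s$rref_end[i])
      } else {
        out[[length(out) + 1L]] <- c(cs, ce, rid)
        cs <- s$rref_start[i]; ce <- s$rref_end[i]
      }
    }
    out[[length(out) + 1L]] <- c(cs, ce, rid)
  }
  m <- do.call(rbind, out)
  data.frame(chrom = chrom, rref_start = as.integer(m[, 1]),
             rref_end = as.integer(m[, 2]), source = "cigar",
             read_id = m[, 3])
}

#' Segment alignments of split reads
#'
#' Restricts an alignment table to reads with at least two records and
#' returns their aligned segments as `SegmentAlignment` rows; query
#' coordinates are already in the forward-read frame.
#'
#' @param aln Alignment table from [alignment_table()].
#' @return Data frame of segments sorted by read then query position.
#' @export
split_segments <- function(aln) {
  seg <- aln[aln$n_segments >= 2L,
             c("read_id", "strand", "ref_start", "ref_end", "read_start",
               "read_end"), drop = FALSE]
  seg[order(seg$read_id, seg$read_start), , drop = FALSE]
}

#' Split-alignment distance between two segments of one read
#'
#' For two segments of the same read, on the same chromosome and strand,
#' with `seg1` preceding `seg2` on both read and reference:
#' `Distance = (ref2_start - ref1_end) - (read2_start - read1_end)`.
#' A deletion sub-signature `(ref1_end, ref1_end + Distance)` is emitted
#' iff `Distance > 40`.
#'
#' @param seg1,seg2 Single-row segment data frames (or lists) with fields
#'   `read_id`, `strand`, `ref_start`, `ref_end`, `read_start`, `read_end`.
#' @param chrom Chromosome name for the emitted signature.
#' @param min_distance Strict threshold, default 40 bp.
#' @return List with `distance` (or `NA` when the preconditions fail) and
#'   `signature` (one-row data frame or `NULL`).
#' @export
split_distance <- function(seg1, seg2, chrom = "chr", min_distance = 40L) {
  ok <- seg1$read_id == seg2$read_id && seg1$strand == seg2$strand &&
    seg1$read_end <= seg2$read_start && seg1$ref_end <= seg2$ref_start
  if (!ok) return(list(distance = NA_integer_, signature = NULL))
  d <- (seg2$ref_start - seg1$ref_end) - (seg2$read_start - seg1$read_end)
  sig <- NULL
  if (d > min_distance)
    sig <- data.frame(chrom = chrom, rref_start = seg1$ref_end,
                      rref_end = seg1$ref_end + d, source = "split",
                      read_id = seg1$read_id)
  list(distance = d, signature = sig)
}

#' Split-read sub-signatures for a whole segment table
#'
#' Applies [split_distance()] to every pair of reference-adjacent segments
#' (consecutive on both read and reference, same strand) of each split
#' read.
#'
#' @param segs Output of [split_segments()].
#' @param chrom Chromosome name.
#' @return Data frame of sub-signatures (`source = "split"`).
#' @export
split_read_signatures <- function(segs, chrom) {
  out <- list()
  for (rid in unique(segs$read_id)) {
    s <- segs[segs$read_id == rid, , drop = FALSE]
    s <- s[order(s$read_start), , drop = FALSE]
    for (i in seq_len(nrow(s) - 1L)) {
      r <- split_distance(s[i, ], s[i + 1L, ], chrom)
      if (!is.null(r$signature)) out[[length(out) + 1L]] <- r$signature
    }
  }
  if (length(out) == 0L) return(.empty_signatures())
  do.call(rbind, out)
}

#' Cluster sorted sub-signatures into bins
#'
#' Chained single-linkage over the sorted stream: a signature joins the
#' current bin iff it is on the same chromosome and both its start and end
#' are within `max_dist` (1500 bp) of the bin's most recent member;
#' otherwise it opens a new bin.
#'
#' @param sigs Sub-signature data frame.
#' @param max_dist Linkage distance, default 1500 bp.
#' @return `sigs` sorted by (`chrom`, `rref_start`) with a `bin` column.
#' @export
cluster_signatures <- function(sigs, max_dist = 1500L) {
  if (nrow(sigs) == 0L) return(cbind(sigs, bin = integer(0)))
  sigs <- sigs[order(sigs$chrom, sigs$rref_start, sigs$rref_end), ,
               drop = FALSE]
  bin <- integer(nrow(sigs))
  bin[1] <- 1L
  for (i in seq_len(nrow(sigs))[-1]) {
    same <- sigs$chrom[i] == sigs$chrom[i - 1L] &&
      abs(sigs$rref_start[i] - sigs$rref_start[i - 1L]) <= max_dist &&
      abs(sigs$rref_end[i] - sigs$rref_end[i - 1L]) <= max_dist
    bin[i] <- if (same) bin[i - 1L] else bin[i - 1L] + 1L
  }
  sigs$bin <- bin
  sigs
}

#' Summarise one signature bin into a deletion call
#'
#' Start is the lower median of the member starts, length the lower median
#' of the member lengths, end = start + length. The call is emitted only
#' if it is supported by at least `min_support` distinct reads and is at
#' least 50 bp long.
#'
#' @param bin_sigs Sub-signatures of one bin.
#' @param min_support Minimum distinct supporting reads.
#' @param min_size Minimum deletion length, default 50 bp.
#' @return One-row data frame (`chrom`, `start`, `end`, `length`,
#'   `support`) or `NULL`.
#' @export
finalize_call <- function(bin_sigs, min_support = 1L, min_size = 50L) {
  stopifnot(nrow(bin_sigs) >= 1L)
  support <- length(unique(bin_sigs$read_id))
  start <- .lower_median(bin_sigs$rref_start)
  len <- .lower_median(bin_sigs$rref_end - bin_sigs$rref_start)
  if (support < min_support || len < min_size) return(NULL)
  data.frame(chrom = bin_sigs$chrom[1], start = as.integer(start),
             end = as.integer(start + len), length = as.integer(len),
             support = as.integer(support))
}

#' Refine flagged sub-regions into deletion calls
#'
#' Full deterministic chain: collect CIGAR and split-read sub-signatures
#' from every flagged sub-region, de-duplicate, sort, cluster with the
#' 1500 bp rule and summarise each bin.
#'
#' @param aln Alignment table for the chromosome.
#' @param flagged Data frame of flagged sub-regions (`start`, `end`,
#'   optionally `prob`).
#' @param chrom Chromosome name.
#' @param min_support Minimum distinct supporting reads per call.
#' @return Data frame of calls sorted by start, with a `probability`
#'   column (max flagged-tile probability overlapping the call) when
#'   `flagged$prob` is present.
#' @export
refine_breakpoints <- function(aln, flagged, chrom, min_support = 3L) {
  sig_list <- vector("list", nrow(flagged))
  segs <- split_segments(aln)
  split_sigs <- split_read_signatures(segs, chrom)
  for (i in seq_len(nrow(flagged))) {
    cs <- cigar_deletion_signatures(aln, chrom, flagged$start[i],
                                    flagged$end[i])
    ## keep split signatures attributable to this flagged tile
    ss <- split_sigs[split_sigs$rref_start < flagged$end[i] + 200L &
                       split_sigs$rref_end > flagged$start[i] - 200L, ,
                     drop = FALSE]
    sig_list[[i]] <- rbind(cs, ss)
  }
  sigs <- do.call(rbind, sig_list)
  if (is.null(sigs) || nrow(sigs) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      support = integer(0), probability = numeric(0)))
  sigs <- unique(sigs)
  cl <- cluster_signatures(sigs)
  calls <- do.call(rbind, lapply(split(cl, cl$bin), finalize_call,
                                 min_support = min_support))
  if (is.null(calls) || nrow(calls) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      support = integer(0), probability = numeric(0)))
  calls <- calls[order(calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  if (!is.null(flagged$prob)) {
    calls$probability <- vapply(seq_len(nrow(calls)), function(i) {
      ov <- flagged$start < calls$end[i] & flagged$end > calls$start[i]
      if (any(ov)) max(flagged$prob[ov]) else NA_real_
    }, numeric(1))
  } else calls$probability <- NA_real_
  calls
}
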