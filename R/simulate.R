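## Synthetic diploid alignment simulator.
##
## Emits exactly the evidence classes the feature extractor and the
## breakpoint heuristic consume: interior D CIGAR ops for deletions up to
## d_op_max, primary + supplementary split pairs for larger ones, soft
## clips at breakpoints (long reads with short anchors, and short reads
## crossing a junction), plus substitution sequencing errors. Alignments
## are synthesised directly against the reference -- no external aligner --
## so signature geometry is exact and fully controlled by the seed.

#' Simulation parameters
#'
#' @param ref_length Reference length in bp.
#' @param n_deletions Number of planted deletions.
#' @param size_range Deletion size range in bp (uniform draw), minimum 50.
#' @param het_fraction Fraction of deletions that are heterozygous.
#' @param long_coverage,short_coverage Haploid-summed sequencing depths.
#'   `short_coverage = 0` disables short reads.
#' @param long_read_mean_len Mean long-read length (clipped normal, sd 15%).
#' @param short_read_len Fixed short-read length.
#' @param d_op_max Deletions up to this size are encoded as one CIGAR `D`
#'   op; larger ones as split primary + supplementary alignments.
#' @param base_error_rate Per-base substitution error rate in read
#'   sequences (CIGARs are unaffected; errors are substitutions only).
#' @param min_anchor Minimum aligned bases a read must have on one side of
#'   a junction; shorter terminal segments are soft-clipped away.
#' @param sizes Optional explicit deletion sizes (length `n_deletions`),
#'   overriding `size_range` draws.
#' @param seed Integer seed governing every random draw.
#' @return A named list of class `simulation_spec`.
#' @export
simulation_spec <- function(ref_length = 2000000L, n_deletions = 40L,
                            size_range = c(50L, 5000L), het_fraction = 0.5,
                            long_coverage = 30, short_coverage = 40,
                            long_read_mean_len = 8000L, short_read_len = 250L,
                            d_op_max = 1000L, base_error_rate = 0.02,
                            min_anchor = 30L, sizes = NULL, seed = 1L) {
  stopifnot(ref_length > 0, n_deletions >= 0, size_range[1] >= 50,
            size_range[1] <= size_range[2],
            het_fraction >= 0, het_fraction <= 1,
            base_error_rate >= 0, base_error_rate <= 1,
            is.null(sizes) || (length(sizes) == n_deletions &&
                                 all(sizes >= 50)))
  structure(as.list(environment()), class = "simulation_spec")
}

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

## substitution errors over a character vector of sequences, vectorised via
## one concatenated raw buffer
.add_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  r <- charToRaw(paste(seqs, collapse = ""))
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err > 0) {
    pos <- sample.int(total, n_err)
    lut <- integer(256)
    lut[as.integer(charToRaw("ACGT"))] <- 0:3
    old <- lut[as.integer(r[pos]) + 1L]
    ## map A->0.., shift by 1..3, back: never silent
    new <- (lut[as.integer(r[pos])] + sample.int(3L, n_err, replace = TRUE)) %% 4L
    r[pos] <- charToRaw("ACGT")[new + 1L]
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  substring(rawToChar(r), starts, ends)
}

#' Simulate a diploid genome with planted deletions
#'
#' Deletions are placed one per equal-width slot of the reference (with a
#' 50 bp guard band), so they are non-overlapping and at least 50 bp apart
#' by construction. Homozygous deletions are removed from both haplotypes,
#' heterozygous ones from a randomly chosen single haplotype.
#'
#' @param spec A [simulation_spec()].
#' @return List with `reference` (character), `truth` (data.frame `chrom`,
#'   `start`, `end`, `zygosity`, 0-based half-open), `haplotypes` (two
#'   character strings) and internal coordinate maps used by the read
#'   simulators.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  reference <- .random_dna(spec$ref_length)
  n <- spec$n_deletions
  truth <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), zygosity = character(0))
  if (n > 0) {
    slot <- spec$ref_length %/% n
    if (is.null(spec$sizes)) {
      size_pool <- seq.int(spec$size_range[1], spec$size_range[2])
      sizes <- size_pool[sample.int(length(size_pool), n, replace = TRUE)]
    } else {
      sizes <- as.integer(spec$sizes)
    }
    if (any(sizes + 100L > slot))
      stop("infeasible packing: too many/large deletions for ref_length")
    slack <- slot - sizes - 100L
    starts <- (seq_len(n) - 1L) * slot + 50L +
      floor(stats::runif(n) * (slack + 1L))
    zyg <- rep("hom", n)
    zyg[sample.int(n, round(spec$het_fraction * n))] <- "het"
    truth <- data.frame(chrom = "chrS", start = as.integer(starts),
                        end = as.integer(starts + sizes), zygosity = zyg)
  }
  het_hap <- ifelse(truth$zygosity == "het",
                    sample(1:2, nrow(truth), replace = TRUE), 0L)
  haps <- vector("list", 2L)
  maps <- vector("list", 2L)
  for (h in 1:2) {
    del <- truth[truth$zygosity == "hom" | het_hap == h, , drop = FALSE]
    maps[[h]] <- .kept_map(del, spec$ref_length)
    haps[[h]] <- .apply_deletions(reference, del)
  }
  list(reference = reference, truth = truth, haplotypes = haps, maps = maps,
       spec = spec)
}

## kept (non-deleted) reference intervals for one haplotype and their
## cumulative haplotype-space starts
.kept_map <- function(del, ref_length) {
  del <- del[order(del$start), , drop = FALSE]
  rs <- c(0L, del$end)
  re <- c(del$start, ref_length)
  keep <- re > rs
  rs <- rs[keep]; re <- re[keep]
  w <- re - rs
  hs <- cumsum(c(0L, w))[seq_along(w)]
  list(ref_start = rs, ref_end = re, width = w, hap_start = hs,
       hap_length = sum(w))
}

.apply_deletions <- function(reference, del) {
  if (nrow(del) == 0L) return(reference)
  del <- del[order(del$start), , drop = FALSE]
  ks <- c(0L, del$end); ke <- c(del$start, nchar(reference))
  keep <- ke > ks
  paste(substring(reference, ks[keep] + 1L, ke[keep]), collapse = "")
}

## map a haplotype interval [s, e) to reference-aligned segments
## returns data.frame(qs, qe, rs, re): q = read-local coords (forward frame)
.hap_to_ref_segments <- function(s, e, map) {
  i1 <- findInterval(s, map$hap_start)
  i2 <- findInterval(e - 1L, map$hap_start)
  idx <- i1:i2
  hs <- map$hap_start[idx]
  qs <- pmax(s, hs); qe <- pmin(e, hs + map$width[idx])
  data.frame(qs = qs - s, qe = qe - s,
             rs = map$ref_start[idx] + (qs - hs),
             re = map$ref_start[idx] + (qe - hs))
}

.sam_fields <- function() {
  c("qname", "flag", "rname", "pos", "mapq", "cigar", "rnext", "pnext",
    "tlen", "seq", "qual")
}

.empty_sam <- function() {
  as.data.frame(stats::setNames(
    list(character(0), integer(0), character(0), integer(0), integer(0),
         character(0), character(0), integer(0), integer(0), character(0),
         character(0)), .sam_fields()))
}

## records for one long read crossing >= 1 junction
.long_read_records <- function(qname, seqfull, strand, segs, d_op_max,
                               min_anchor) {
  readlen <- nchar(seqfull)
  ## soft-clip away sub-anchor terminal segments
  while (nrow(segs) > 1L && segs$qe[1] - segs$qs[1] < min_anchor)
    segs <- segs[-1L, , drop = FALSE]
  while (nrow(segs) > 1L && segs$qe[nrow(segs)] - segs$qs[nrow(segs)] < min_anchor)
    segs <- segs[-nrow(segs), , drop = FALSE]
  gaps <- if (nrow(segs) > 1L) segs$rs[-1L] - segs$re[-nrow(segs)] else integer(0)
  grp <- cumsum(c(1L, as.integer(gaps > d_op_max)))
  out <- .empty_sam()
  aligned <- tapply(segs$qe - segs$qs, grp, sum)
  primary_grp <- as.integer(names(aligned))[which.max(aligned)]
  for (g in unique(grp)) {
    sg <- segs[grp == g, , drop = FALSE]
    q0 <- sg$qs[1]; q1 <- sg$qe[nrow(sg)]
    body <- character(0)
    for (k in seq_len(nrow(sg))) {
      body <- c(body, paste0(sg$qe[k] - sg$qs[k], "M"))
      if (k < nrow(sg)) body <- c(body, paste0(sg$rs[k + 1L] - sg$re[k], "D"))
    }
    body <- paste(body, collapse = "")
    is_primary <- (g == primary_grp)
    ## SAM stores CIGAR and SEQ in reference orientation, so clip sides and
    ## the sequence are identical for both strands; only the flag differs
    lc <- q0; rc <- readlen - q1
    ctype <- if (is_primary) "S" else "H"
    cig <- paste0(if (lc > 0) paste0(lc, ctype) else "", body,
                  if (rc > 0) paste0(rc, ctype) else "")
    sq <- if (is_primary) seqfull else substring(seqfull, q0 + 1L, q1)
    flag <- (if (strand == "-") 16L else 0L) + (if (is_primary) 0L else 2048L)
    out <- rbind(out, data.frame(qname = qname, flag = flag, rname = "chrS",
                                 pos = sg$rs[1] + 1L, mapq = 60L, cigar = cig,
                                 rnext = "*", pnext = 0L, tlen = 0L, seq = sq,
                                 qual = "*"))
  }
  out
}

#' Simulate long-read alignment records
#'
#' Draws reads uniformly from both haplotypes at `long_coverage/2` each.
#' Reads spanning a deletion of size `<= d_op_max` carry one interior `D`
#' op of exactly that size; reads spanning a larger deletion are emitted as
#' a soft-clipped primary plus hard-clipped supplementary record whose
#' split distance equals the deletion length. Terminal anchors shorter than
#' `min_anchor` become soft clips at the breakpoint.
#'
#' @param genome Result of [simulate_genome()].
#' @return Data frame of SAM records (unsorted).
#' @export
simulate_long_alignments <- function(genome) {
  spec <- genome$spec
  out <- list()
  for (h in 1:2) {
    map <- genome$maps[[h]]
    hap <- genome$haplotypes[[h]]
    hlen <- map$hap_length
    n <- ceiling(spec$long_coverage / 2 * spec$ref_length /
                   spec$long_read_mean_len)
    lens <- as.integer(pmin(pmax(round(stats::rnorm(
      n, spec$long_read_mean_len, 0.15 * spec$long_read_mean_len)),
      500L), hlen))
    starts <- as.integer(floor(stats::runif(n) * (hlen - lens + 1)))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- .add_errors(substring(hap, starts + 1L, starts + lens),
                        spec$base_error_rate)
    ## junctions in haplotype coordinates (deletion sites)
    js <- map$hap_start[-1L]
    crosses <- if (length(js))
      (findInterval(starts + lens - 1L, js) - findInterval(starts, js)) > 0
    else rep(FALSE, n)
    qn <- sprintf("simL_h%d_%06d", h, seq_len(n))
    ## simple reads: one M record
    if (any(!crosses)) {
      i <- which(!crosses)
      ki <- findInterval(starts[i], map$hap_start)
      pos1 <- map$ref_start[ki] + (starts[i] - map$hap_start[ki]) + 1L
      sq <- seqs[i]
      neg <- strands[i] == "-"
      out[[length(out) + 1L]] <- data.frame(
        qname = qn[i], flag = ifelse(neg, 16L, 0L), rname = "chrS",
        pos = pos1, mapq = 60L, cigar = paste0(lens[i], "M"), rnext = "*",
        pnext = 0L, tlen = 0L, seq = sq, qual = "*")
    }
    for (i in which(crosses)) {
      segs <- .hap_to_ref_segments(starts[i], starts[i] + lens[i], map)
      out[[length(out) + 1L]] <- .long_read_records(
        qn[i], seqs[i], strands[i], segs, spec$d_op_max, spec$min_anchor)
    }
  }
  do.call(rbind, out)
}

#' Simulate paired short-read alignment records
#'
#' Fixed-length paired reads from both haplotypes. A read crossing a
#' deletion junction is soft-clipped at the junction: the longer aligned
#' side is kept as `M`, so clip boundaries concentrate exactly at the
#' breakpoints.
#'
#' @param genome Result of [simulate_genome()].
#' @return Data frame of SAM records (unsorted); empty if
#'   `short_coverage == 0`.
#' @export
simulate_short_alignments <- function(genome) {
  spec <- genome$spec
  rl <- spec$short_read_len
  if (spec$short_coverage <= 0) return(.empty_sam())
  out <- list()
  for (h in 1:2) {
    map <- genome$maps[[h]]
    hap <- genome$haplotypes[[h]]
    hlen <- map$hap_length
    n_pairs <- ceiling(spec$short_coverage / 2 * spec$ref_length / (2 * rl))
    frag <- as.integer(pmin(pmax(round(stats::rnorm(n_pairs, 450, 50)),
                                 2L * rl + 10L), hlen))
    fstart <- as.integer(floor(stats::runif(n_pairs) * (hlen - frag + 1)))
    ## R1 forward at fragment start, R2 reverse at fragment end
    s <- c(fstart, fstart + frag - rl)
    strand <- rep(c("+", "-"), each = n_pairs)
    flagbase <- rep(c(99L, 147L), each = n_pairs)   # proper pair, R1/R2
    qn <- rep(sprintf("simS_h%d_%07d", h, seq_len(n_pairs)), 2L)
    seqs <- .add_errors(substring(hap, s + 1L, s + rl), spec$base_error_rate)
    js <- map$hap_start[-1L]
    crosses <- if (length(js))
      (findInterval(s + rl - 1L, js) - findInterval(s, js)) > 0
    else rep(FALSE, 2L * n_pairs)
    pos1 <- integer(2L * n_pairs)
    cig <- character(2L * n_pairs)
    i <- which(!crosses)
    ki <- findInterval(s[i], map$hap_start)
    pos1[i] <- map$ref_start[ki] + (s[i] - map$hap_start[ki]) + 1L
    cig[i] <- paste0(rl, "M")
    for (i in which(crosses)) {
      segs <- .hap_to_ref_segments(s[i], s[i] + rl, map)
      ## clip at the junction adjacent to the longer aligned piece;
      ## clip sides are in reference order (same for both strands)
      w <- segs$qe - segs$qs
      k <- which.max(w)
      lc <- segs$qs[k]; rc <- rl - segs$qe[k]
      cig[i] <- paste0(if (lc > 0) paste0(lc, "S") else "",
                       w[k], "M",
                       if (rc > 0) paste0(rc, "S") else "")
      pos1[i] <- segs$rs[k] + 1L
    }
    neg <- strand == "-"
    mate_pos <- c(pos1[(n_pairs + 1L):(2L * n_pairs)], pos1[seq_len(n_pairs)])
    out[[length(out) + 1L]] <- data.frame(
      qname = qn, flag = flagbase + ifelse(neg & flagbase == 99L, 16L, 0L),
      rname = "chrS", pos = pos1, mapq = 60L, cigar = cig, rnext = "=",
      pnext = mate_pos, tlen = 0L, seq = seqs, qual = "*")
  }
  do.call(rbind, out)
}

#' Write SAM records and convert to a sorted, indexed BAM
#'
#' @param records Data frame of SAM records.
#' @param chrom,chrom_length Contig for the header.
#' @param bam_path Output path (without extension additions); the sorted
#'   BAM lands at `bam_path` with a `.bai` index beside it.
#' @return `bam_path`, invisibly.
#' @export
write_alignments_bam <- function(records, chrom, chrom_length, bam_path) {
  ## integer coercion guards against scientific notation in the SAM text
  for (cl in c("flag", "pos", "mapq", "pnext", "tlen"))
    records[[cl]] <- as.integer(records[[cl]])
  records <- records[order(records$pos, records$qname, records$flag), ,
                     drop = FALSE]
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", chrom, "\tLN:", chrom_length))
  lines <- do.call(paste, c(as.list(records[.sam_fields()]), sep = "\t"))
  writeLines(c(header, lines), sam)
  tmp <- Rsamtools::asBam(sam, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(tmp, destination = sub("\\.bam$", "", bam_path))
  unlink(tmp)
  Rsamtools::indexBam(sorted)
  invisible(sorted)
}

#' Simulate a complete dataset on disk
#'
#' Runs [simulate_genome()] and both read simulators, then writes
#' `ref.fa` (+ `.fai`), `truth.bed` (0-based half-open, with a zygosity
#' column), `long.bam` and (unless `short_coverage == 0`) `short.bam`,
#' all sorted and indexed.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return List with file paths, the truth data frame and the genome.
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(spec)
  ref_fa <- file.path(dir, "ref.fa")
  dna <- Biostrings::DNAStringSet(genome$reference)
  names(dna) <- "chrS"
  Biostrings::writeXStringSet(dna, ref_fa)
  Rsamtools::indexFa(ref_fa)
  truth_bed <- file.path(dir, "truth.bed")
  utils::write.table(genome$truth, truth_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  long_bam <- file.path(dir, "long.bam")
  write_alignments_bam(simulate_long_alignments(genome), "chrS",
                       spec$ref_length, long_bam)
  short_bam <- NULL
  if (spec$short_coverage > 0) {
    short_bam <- file.path(dir, "short.bam")
    write_alignments_bam(simulate_short_alignments(genome), "chrS",
                         spec$ref_length, short_bam)
  }
  list(ref_fa = ref_fa, truth_bed = truth_bed, long_bam = long_bam,
       short_bam = short_bam, truth = genome$truth, genome = genome)
}

#' Read a truth BED written by [simulate_dataset()]
#' @param path Path to the BED file.
#' @return Data frame `chrom`, `start`, `end`, `zygosity`.
#' @export
read_truth_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "zygosity")
  df
}
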