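# Build tiny BAM fixtures from record tables, fully in code.

# records: data.frame(qname, flag, pos (1-based), cigar[, mapq, seq])
make_bam <- function(records, chrom = "chr1", chrom_length = 2000L,
                     path = tempfile(fileext = ".bam")) {
  if (is.null(records$mapq)) records$mapq <- 60L
  if (is.null(records$seq)) {
    qlen <- vapply(records$cigar, cigar_query_len, integer(1),
                   USE.NAMES = FALSE)
    records$seq <- vapply(qlen, function(n)
      paste(rep("A", max(n, 1L)), collapse = ""), character(1))
  }
  records <- records[order(records$pos), , drop = FALSE]
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", chrom, "\tLN:", chrom_length),
    paste(records$qname, records$flag, chrom, records$pos, records$mapq,
          records$cigar, "*", 0L, 0L, records$seq, "*", sep = "\t")), sam)
  tmp <- Rsamtools::asBam(sam, destination = tempfile(),
                          indexDestination = FALSE, overwrite = TRUE)
  out <- Rsamtools::sortBam(tmp, destination = sub("\\.bam$", "", path))
  unlink(tmp)
  Rsamtools::indexBam(out)
  out
}

parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

cigar_query_len <- function(cigar) {
  p <- parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
}

cigar_ref_len <- function(cigar) {
  p <- parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
}

# random single-chromosome record set exercising M/D/I/S/H ops, split
# (supplementary) pairs, strands, and filtered flags
random_records <- function(n_reads = 20L, chrom_length = 2000L) {
  recs <- list()
  for (i in seq_len(n_reads)) {
    qn <- sprintf("r%03d", i)
    kind <- sample(c("plain", "del", "clip", "split", "filtered"), 1L,
                   prob = c(.3, .25, .2, .15, .1))
    pos <- sample.int(chrom_length %/% 2L, 1L)
    strand_flag <- sample(c(0L, 16L), 1L)
    if (kind == "plain") {
      cig <- paste0(sample(50:200, 1L), "M")
      recs[[length(recs) + 1L]] <- data.frame(
        qname = qn, flag = strand_flag, pos = pos, cigar = cig, mapq = 60L)
    } else if (kind == "del") {
      cig <- paste0(sample(30:100, 1L), "M", sample(c(10:80), 1L), "D",
                    sample(30:100, 1L), "M")
      recs[[length(recs) + 1L]] <- data.frame(
        qname = qn, flag = strand_flag, pos = pos, cigar = cig, mapq = 60L)
    } else if (kind == "clip") {
      lc <- sample(c(0L, 5L, 15L, 40L), 1L); rc <- sample(c(0L, 5L, 25L), 1L)
      cig <- paste0(if (lc) paste0(lc, "S") else "", sample(40:150, 1L), "M",
                    if (rc) paste0(rc, "S") else "")
      recs[[length(recs) + 1L]] <- data.frame(
        qname = qn, flag = strand_flag, pos = pos, cigar = cig, mapq = 60L)
    } else if (kind == "split") {
      m1 <- sample(40:120, 1L); m2 <- sample(40:120, 1L)
      gap <- sample(50:400, 1L)
      recs[[length(recs) + 1L]] <- data.frame(
        qname = qn, flag = strand_flag, pos = pos,
        cigar = paste0(m1, "M", m2, "S"), mapq = 60L)
      recs[[length(recs) + 1L]] <- data.frame(
        qname = qn, flag = strand_flag + 2048L,
        pos = pos + m1 + gap,
        cigar = paste0(m1, "H", m2, "M"), mapq = 60L)
    } else {
      bad_flag <- sample(c(256L, 1024L), 1L)
      bad_mapq <- sample(c(5L, 60L), 1L)
      recs[[length(recs) + 1L]] <- data.frame(
        qname = qn, flag = if (bad_mapq == 60L) bad_flag else strand_flag,
        pos = pos, cigar = paste0(sample(50:150, 1L), "M"), mapq = bad_mapq)
    }
  }
  do.call(rbind, recs)
}
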