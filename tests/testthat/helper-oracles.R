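# Independent brute-force implementations used as oracles. They parse
# record tables directly and expand every CIGAR op position by position,
# sharing no code with the package's coverage-Rle implementation.

# nine signature tracks from a record table (one read class)
oracle_class_tracks <- function(records, chrom_length, min_mapq = 20L,
                                min_clip = 10L, split_counts = TRUE) {
  z <- numeric(chrom_length)
  tr <- list(cov = z, del = z, lb = z, rb = z, sp = z)
  keep <- records$mapq >= min_mapq &
    bitwAnd(records$flag, 4L) == 0L &
    bitwAnd(records$flag, 256L) == 0L &
    bitwAnd(records$flag, 1024L) == 0L
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) return(tr)
  spans <- matrix(0L, nrow(records), 2L)
  for (i in seq_len(nrow(records))) {
    p <- parse_cigar(records$cigar[i])
    ref0 <- records$pos[i] - 1L            # 0-based walk
    start0 <- ref0
    for (j in seq_along(p$op)) {
      op <- p$op[j]; len <- p$len[j]
      if (op %in% c("M", "=", "X")) {
        ref0 <- ref0 + len
      } else if (op %in% c("D", "N")) {
        if (op == "D")
          for (q in ref0:(ref0 + len - 1L))
            if (q < chrom_length) tr$del[q + 1L] <- tr$del[q + 1L] + 1
        ref0 <- ref0 + len
      }
    }
    end0 <- ref0                           # exclusive
    spans[i, ] <- c(start0, end0)
    for (q in start0:(end0 - 1L))
      if (q < chrom_length) tr$cov[q + 1L] <- tr$cov[q + 1L] + 1
    if (p$op[1] %in% c("S", "H") && p$len[1] >= min_clip)
      tr$rb[start0 + 1L] <- tr$rb[start0 + 1L] + 1
    last <- length(p$op)
    if (p$op[last] %in% c("S", "H") && p$len[last] >= min_clip)
      tr$lb[end0] <- tr$lb[end0] + 1
  }
  if (split_counts) {
    tab <- table(records$qname)
    for (i in seq_len(nrow(records))) {
      if (tab[[records$qname[i]]] >= 2L) {
        tr$sp[spans[i, 1] + 1L] <- tr$sp[spans[i, 1] + 1L] + 1
        tr$sp[spans[i, 2]] <- tr$sp[spans[i, 2]] + 1
      }
    }
  }
  tr
}

oracle_tracks <- function(long_records, short_records, chrom_length,
                          block_size = 10000000L) {
  lt <- oracle_class_tracks(long_records, chrom_length)
  st <- if (is.null(short_records)) {
    z <- numeric(chrom_length)
    list(cov = z, lb = z, rb = z)
  } else oracle_class_tracks(short_records, chrom_length,
                             split_counts = FALSE)
  lm <- numeric(chrom_length)
  bstart <- seq.int(0L, chrom_length - 1L, by = block_size)
  for (b in bstart) {
    e <- min(b + block_size, chrom_length)
    lm[(b + 1L):e] <- mean(lt$cov[(b + 1L):e])
  }
  m <- rbind(lt$cov, lt$del, lt$lb, lt$rb, lt$sp, lm, st$cov, st$lb, st$rb)
  rownames(m) <- c("read_lc", "read_ld", "read_llb", "read_lrb", "read_lsp",
                   "read_lm", "read_sc", "read_slb", "read_srb")
  m
}

# brute-force CIGAR deletion sub-signatures for one flagged region
oracle_cigar_sigs <- function(records, region_start, region_end,
                              min_d = 30L, max_dist = 200L, gap = 20L) {
  sigs <- list()
  for (i in seq_len(nrow(records))) {
    p <- parse_cigar(records$cigar[i])
    ref0 <- records$pos[i] - 1L
    rs <- ref0
    re <- rs + sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
    if (!(rs < region_end && re > region_start)) next
    cur <- NULL
    for (j in seq_along(p$op)) {
      op <- p$op[j]; len <- p$len[j]
      if (op == "D" && len > min_d && abs(ref0 - region_start) < max_dist) {
        if (!is.null(cur) && ref0 - cur[2] < gap) {
          cur[2] <- ref0 + len
        } else {
          if (!is.null(cur))
            sigs[[length(sigs) + 1L]] <- c(cur, records$qname[i])
          cur <- c(ref0, ref0 + len)
        }
      }
      if (op %in% c("M", "D", "N", "=", "X")) ref0 <- ref0 + len
    }
    if (!is.null(cur)) sigs[[length(sigs) + 1L]] <- c(cur, records$qname[i])
  }
  if (length(sigs) == 0L)
    return(data.frame(rref_start = integer(0), rref_end = integer(0),
                      read_id = character(0)))
  m <- do.call(rbind, sigs)
  out <- data.frame(rref_start = as.integer(m[, 1]),
                    rref_end = as.integer(m[, 2]), read_id = m[, 3])
  out[order(out$read_id, out$rref_start), , drop = FALSE]
}

# transitive-closure clustering under the 1500 bp rule
oracle_cluster <- function(sigs, max_dist = 1500L) {
  n <- nrow(sigs)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          sigs$chrom[i] == sigs$chrom[j] &&
          abs(sigs$rref_start[i] - sigs$rref_start[j]) <= max_dist &&
          abs(sigs$rref_end[i] - sigs$rref_end[j]) <= max_dist) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# membership partition as a canonical set of sorted index vectors
partition_sets <- function(ids) {
  unname(lapply(split(seq_along(ids), ids), sort))
}

# random sub-signature set: well-separated clusters with internal jitter
random_signatures <- function(n_clusters = 3L, max_members = 5L) {
  out <- NULL
  pos <- 0L
  for (k in seq_len(n_clusters)) {
    pos <- pos + sample(4000:10000, 1L)
    n <- sample.int(max_members, 1L)
    s <- pos + sample.int(1200L, n, replace = TRUE)
    l <- sample(60:1300, 1L) + sample.int(200L, n, replace = TRUE)
    out <- rbind(out, data.frame(
      chrom = sample(c("chr1", "chr2"), 1L),
      rref_start = as.integer(s), rref_end = as.integer(s + l),
      source = "cigar",
      read_id = sprintf("c%dm%d", k, seq_len(n))))
  }
  out
}
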