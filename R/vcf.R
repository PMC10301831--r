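## VCF 4.2 emission and re-parsing for deletion calls. Internally
## coordinates are 0-based half-open; POS in the VCF is the 1-based first
## deleted base and END the 1-based last deleted base (equal to the
## internal exclusive end).

#' Write deletion calls to a VCF 4.2 file
#'
#' @param calls Data frame with `chrom`, `start`, `end`, `length`,
#'   `support`, `genotype` (`"0/1"`/`"1/1"`), `probability`; must be
#'   sorted by (`chrom`, `start`).
#' @param contigs Named integer vector of contig lengths for the header.
#' @param path Output path.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, contigs, path, sample = "SAMPLE") {
  if (nrow(calls) > 1L) {
    o <- order(calls$chrom, calls$start)
    if (!identical(o, seq_len(nrow(calls))))
      stop("calls must be sorted by (chrom, start)")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
    paste0("##source=deepdel-", as.character(utils::packageVersion("deepdel"))),
    paste0("##contig=<ID=", names(contigs), ",length=", contigs, ">"),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=PROB,Number=1,Type=Float,Description=\"Classifier probability\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  recs <- character(0)
  if (nrow(calls) > 0L) {
    gt <- if (is.null(calls$genotype)) rep("./.", nrow(calls)) else
      calls$genotype
    prob <- if (is.null(calls$probability)) rep(NA_real_, nrow(calls)) else
      calls$probability
    info <- paste0("SVTYPE=DEL;END=", calls$end, ";SVLEN=-", calls$length,
                   ";SUPPORT=", calls$support,
                   ifelse(is.na(prob), "",
                          paste0(";PROB=", formatC(prob, digits = 4,
                                                   format = "f"))))
    recs <- paste(calls$chrom, calls$start + 1L,
                  paste0("DEL_", seq_len(nrow(calls))), "N", "<DEL>", ".",
                  "PASS", info, "GT", gt, sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Parse a VCF written by [write_vcf()] back into a calls data frame
#'
#' @param path VCF path.
#' @return Data frame with the same columns as the input of [write_vcf()].
#' @export
read_vcf_calls <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (length(ln) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      support = integer(0), genotype = character(0),
                      probability = numeric(0)))
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  get_info <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(?<=", key, "=)[-0-9.]+"), info,
                                  perl = TRUE))
    as.numeric(m)
  }
  data.frame(chrom = f[, 1], start = as.integer(f[, 2]) - 1L,
             end = as.integer(get_info(f[, 8], "END")),
             length = as.integer(-get_info(f[, 8], "SVLEN")),
             support = as.integer(get_info(f[, 8], "SUPPORT")),
             genotype = f[, 10],
             probability = vapply(f[, 8], function(i) {
               p <- get_info(i, "PROB")
               if (length(p)) p else NA_real_
             }, numeric(1), USE.NAMES = FALSE))
}
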