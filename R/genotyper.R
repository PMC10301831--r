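## Genotype assignment. The genotype network scores each tile overlapping
## a call; a probability above 0.5 votes homozygous (1/1), below votes
## heterozygous (0/1); the majority wins and ties (including an exact 0.5)
## resolve to the conservative heterozygous call.

#' Genotype probability for tile matrices
#'
#' @param model Trained genotype `deepdel_model`.
#' @param x A 9 x L matrix or `(9, L, N)` array.
#' @return Numeric vector of P(homozygous), one per tile.
#' @export
genotype_probability <- function(model, x) {
  stopifnot(model$kind == "genotype")
  genotype_forward(model, x, train = FALSE)$probs
}

#' Majority-vote genotype for one deletion call
#'
#' @param probs Genotype probabilities of the tiles overlapping the call
#'   (at least one).
#' @param threshold Vote threshold, default 0.5.
#' @return `"1/1"` if homozygous votes strictly outnumber heterozygous
#'   votes, else `"0/1"`.
#' @export
genotype_vote <- function(probs, threshold = 0.5) {
  if (length(probs) == 0L)
    stop("genotype_vote needs at least one overlapping tile probability")
  hom <- sum(probs > threshold)
  het <- length(probs) - hom
  if (hom > het) "1/1" else "0/1"
}

#' Assign genotypes to deletion calls
#'
#' For each call, featurizes every pass-1 grid tile overlapping
#' `[start, end)`, scores it with the genotype network and takes the
#' majority vote.
#'
#' @param calls Calls data frame from [refine_breakpoints()].
#' @param tracks `signature_tracks` for the chromosome.
#' @param model Trained genotype `deepdel_model`.
#' @return `calls` with a `genotype` column.
#' @export
assign_genotypes <- function(calls, tracks, model) {
  L <- model$cfg$L
  calls$genotype <- vapply(seq_len(nrow(calls)), function(i) {
    ts <- (calls$start[i] %/% L) * L
    starts <- seq.int(ts, calls$end[i] - 1L, by = L)
    regions <- data.frame(start = starts,
                          end = pmin(starts + L, tracks$chrom_length))
    x <- featurize_regions(tracks, regions, L)
    genotype_vote(genotype_probability(model, x), model$cfg$decision_threshold)
  }, character(1))
  calls
}
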