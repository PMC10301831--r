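## High-level orchestration: training-set assembly from a truth set,
## end-to-end calling, and genotype concordance.

#' Label tiles by truth overlap
#'
#' @param regions Tile data frame (`start`, `end`).
#' @param truth Truth data frame (`start`, `end`).
#' @return Integer 0/1 vector: 1 where a tile overlaps any truth deletion.
#' @export
label_tiles <- function(regions, truth) {
  lab <- integer(nrow(regions))
  for (i in seq_len(nrow(truth)))
    lab[regions$start < truth$end[i] & regions$end > truth$start[i]] <- 1L
  lab
}

#' Assemble training sequences for the deletion classifier
#'
#' Tiles the requested range on the pass-1 grid, labels tiles by truth
#' overlap, groups consecutive tiles into sequences of `cfg$seq_len`, and
#' keeps every sequence containing a positive tile plus a deterministic
#' sample of negative-only sequences (`neg_ratio` per positive sequence).
#'
#' @param tracks `signature_tracks`.
#' @param truth Truth deletions (`start`, `end`).
#' @param cfg A [model_config()].
#' @param range_start,range_end Genomic range to draw training data from.
#' @param neg_ratio Negative-only sequences kept per positive sequence.
#' @return List: `x` (9, L, seq_len, B), `labels` (seq_len x B),
#'   `regions` (tiles used, in sequence order).
#' @export
make_training_sequences <- function(tracks, truth, cfg,
                                    range_start = 0L,
                                    range_end = tracks$chrom_length,
                                    neg_ratio = 1) {
  L <- cfg$L; T_ <- cfg$seq_len
  grid <- tile_reference(tracks$chrom_length, L, 0L)
  grid <- grid[grid$start >= range_start & grid$end <= range_end, ,
               drop = FALSE]
  lab <- label_tiles(grid, truth)
  nb <- nrow(grid) %/% T_
  if (nb == 0L) stop("range too small for one sequence of seq_len tiles")
  blk <- rep(seq_len(nb), each = T_)
  grid <- grid[seq_len(nb * T_), , drop = FALSE]
  lab <- lab[seq_len(nb * T_)]
  has_pos <- tapply(lab, blk, max) == 1L
  pos_blocks <- which(has_pos)
  neg_blocks <- which(!has_pos)
  set.seed(cfg$seed + 1L)
  n_neg <- min(length(neg_blocks), ceiling(neg_ratio * length(pos_blocks)))
  keep <- sort(c(pos_blocks, sample(neg_blocks, n_neg)))
  B <- length(keep)
  idx <- unlist(lapply(keep, function(b) which(blk == b)))
  x <- featurize_regions(tracks, grid[idx, , drop = FALSE], L)
  dim(x) <- c(9L, L, T_, B)
  list(x = x, labels = matrix(lab[idx], T_, B),
       regions = grid[idx, , drop = FALSE])
}

#' Assemble genotype training tiles
#'
#' All pass-1 tiles overlapping each truth deletion in the range; label 1
#' for homozygous, 0 for heterozygous deletions.
#'
#' @inheritParams make_training_sequences
#' @param truth Truth deletions with a `zygosity` column (`"het"`/`"hom"`).
#' @return List: `x` (9, L, N), `labels` length-N 0/1 vector.
#' @export
make_genotype_tiles <- function(tracks, truth, cfg, range_start = 0L,
                                range_end = tracks$chrom_length) {
  L <- cfg$L
  tr <- truth[truth$start >= range_start & truth$end <= range_end, ,
              drop = FALSE]
  regions <- NULL; labels <- integer(0)
  for (i in seq_len(nrow(tr))) {
    ts <- (tr$start[i] %/% L) * L
    starts <- seq.int(ts, tr$end[i] - 1L, by = L)
    regions <- rbind(regions,
                     data.frame(start = starts,
                                end = pmin(starts + L, tracks$chrom_length)))
    labels <- c(labels, rep(as.integer(tr$zygosity[i] == "hom"),
                            length(starts)))
  }
  list(x = featurize_regions(tracks, regions, L), labels = labels)
}

#' Call deletions on one chromosome
#'
#' Runs the two-pass tile classifier, refines flagged tiles into
#' breakpoint-exact calls, and (when a genotype model is given) assigns
#' genotypes by majority vote.
#'
#' @param model Trained deletion model.
#' @param tracks `signature_tracks` for the chromosome.
#' @param aln Alignment table from [alignment_table()] (long reads).
#' @param genotype_model Optional trained genotype model.
#' @param min_support Minimum supporting reads per call.
#' @return Calls data frame (`chrom`, `start`, `end`, `length`,
#'   `support`, `probability`[, `genotype`]).
#' @export
call_deletions <- function(model, tracks, aln, genotype_model = NULL,
                           min_support = 3L) {
  flagged <- two_pass_predict(model, tracks)
  calls <- refine_breakpoints(aln, flagged, tracks$chrom, min_support)
  if (!is.null(genotype_model) && nrow(calls) > 0L)
    calls <- assign_genotypes(calls, tracks, genotype_model)
  calls
}

#' Run a complete simulation study
#'
#' The package's desk-scale validation protocol: simulate a diploid sample
#' (2 Mbp reference, 40 deletions of 50-5,000 bp, half heterozygous, 30x
#' long reads plus 40x short reads, 2% substitution error by default),
#' train the deletion and genotype networks on the first half of the
#' chromosome, call deletions over the whole chromosome, genotype them,
#' write a VCF, and score calls and genotypes against the planted truth.
#'
#' @param seed Integer seed governing simulation and training.
#' @param dir Working directory for simulated files and outputs.
#' @param spec A [simulation_spec()]; its `seed` is overridden by `seed`.
#' @param cfg A [model_config()]; its `seed` is overridden by `seed + 1`.
#' @param min_support Minimum supporting reads per call (3 suits 30x
#'   coverage).
#' @param train_fraction Fraction of the chromosome (from the start) used
#'   for training.
#' @return List: `calls`, `truth`, `precision`, `recall`, `f1`,
#'   `gt_concordance`, `vcf` (path), `model`, `genotype_model`,
#'   `flagged` (tile count), and the simulated file paths.
#' @export
run_simulation_study <- function(seed = 1L, dir = tempfile("deepdel_"),
                                 spec = simulation_spec(),
                                 cfg = model_config(epochs = 15L),
                                 min_support = 3L, train_fraction = 0.5) {
  spec$seed <- as.integer(seed)
  cfg$seed <- as.integer(seed) + 1L
  ds <- simulate_dataset(spec, dir)
  ds$genome <- NULL                       # haplotype strings no longer needed
  gc(FALSE)
  tracks <- signature_tracks(ds$long_bam, ds$short_bam, "chrS",
                             spec$ref_length)
  half <- as.integer(spec$ref_length * train_fraction)
  tsq <- make_training_sequences(tracks, ds$truth, cfg, 0L, half)
  model <- train_deletion_model(tsq$x, tsq$labels, cfg)
  rm(tsq); gc(FALSE)
  gt <- make_genotype_tiles(tracks, ds$truth, cfg, 0L, half)
  genotype_model <- train_genotype_model(gt$x, gt$labels, cfg)
  rm(gt); gc(FALSE)
  aln <- alignment_table(ds$long_bam, "chrS", spec$ref_length)
  calls <- call_deletions(model, tracks, aln, genotype_model, min_support)
  vcf <- file.path(dir, "calls.vcf")
  write_vcf(calls, stats::setNames(spec$ref_length, "chrS"), vcf)
  ev <- evaluate_calls(calls, ds$truth)
  list(calls = calls, truth = ds$truth, precision = ev$precision,
       recall = ev$recall, f1 = ev$f1,
       gt_concordance = genotype_concordance(calls, ds$truth, ev$matches),
       matches = ev$matches, vcf = vcf, model = model,
       genotype_model = genotype_model,
       files = ds[c("ref_fa", "truth_bed", "long_bam", "short_bam")])
}

#' Genotype concordance over matched calls
#'
#' @param calls Calls with a `genotype` column.
#' @param truth Truth with a `zygosity` column.
#' @param matches Match table from [evaluate_calls()].
#' @return Fraction of matched calls whose genotype equals the truth
#'   zygosity (`"het"` = `"0/1"`, `"hom"` = `"1/1"`); `NA` if no matches.
#' @export
genotype_concordance <- function(calls, truth, matches) {
  if (nrow(matches) == 0L) return(NA_real_)
  want <- ifelse(truth$zygosity[matches$truth] == "hom", "1/1", "0/1")
  mean(calls$genotype[matches$call] == want)
}
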