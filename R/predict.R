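## Two-pass sliding-window inference. Pass 1 scores the offset-0 tiling,
## pass 2 a tiling shifted by half a tile. A deletion sitting astride a
## pass-1 tile boundary can be missed by pass 1 but caught by pass 2; every
## pass-2 positive then flags both pass-1 tiles it overlaps, and the final
## flag set is the union.

#' Two-pass deletion-tile prediction
#'
#' @param model Trained deletion `deepdel_model`.
#' @param tracks `signature_tracks` for the chromosome.
#' @param threshold Decision threshold (both passes), default from the
#'   model config.
#' @return Data frame of flagged pass-1 tiles: `start`, `end`, `prob`
#'   (maximum of the tile's own pass-1 probability and the probabilities
#'   of pass-2 positives overlapping it).
#' @export
two_pass_predict <- function(model, tracks,
                             threshold = model$cfg$decision_threshold) {
  L <- model$cfg$L
  len <- tracks$chrom_length
  grid1 <- tile_reference(len, L, 0L)
  grid2 <- tile_reference(len, L, L %/% 2L)
  p1 <- .predict_grid(model, tracks, grid1)
  p2 <- .predict_grid(model, tracks, grid2)
  flag_two_pass(grid1, p1, grid2, p2, threshold)
}

## featurize + score a tile grid in bounded-memory chunks
.predict_grid <- function(model, tracks, grid, chunk = 2500L) {
  M <- nrow(grid)
  p <- numeric(M)
  for (i0 in seq.int(1L, M, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, M)
    x <- featurize_regions(tracks, grid[i0:i1, , drop = FALSE], model$cfg$L)
    p[i0:i1] <- predict_subregion_probs(model, x)
    rm(x); gc(FALSE)                      # forward caches are large
  }
  p
}

#' Combine two prediction passes into a flag set
#'
#' Pure set logic, separated from featurization for testing: pass-1
#' positives are kept; each pass-2 positive additionally flags every
#' pass-1 tile it overlaps; the result is the union, on the pass-1 grid.
#'
#' @param grid1,grid2 Tilings (`start`, `end`) of the two passes.
#' @param p1,p2 Per-tile probabilities.
#' @param threshold Decision threshold.
#' @return Flagged subset of `grid1` with a `prob` column.
#' @export
flag_two_pass <- function(grid1, p1, grid2, p2, threshold = 0.5) {
  pos1 <- p1 > threshold
  pos2 <- which(p2 > threshold)
  flagged <- pos1
  prob <- p1
  for (j in pos2) {
    ov <- which(grid1$start < grid2$end[j] & grid1$end > grid2$start[j])
    flagged[ov] <- TRUE
    prob[ov] <- pmax(prob[ov], p2[j])
  }
  out <- grid1[flagged, , drop = FALSE]
  out$prob <- prob[flagged]
  rownames(out) <- NULL
  out
}
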