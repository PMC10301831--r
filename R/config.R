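#' Featurization configuration
#'
#' Collects the tunable parameters of signature extraction into one list.
#'
#' @param L Sub-region (tile) width in bp. Each tile becomes one 9 x `L`
#'   feature matrix and one classification unit.
#' @param min_mapq Minimum mapping quality for a record to be counted.
#' @param min_clip Minimum soft/hard clip length (bp) for a clip to be
#'   counted as a clip-boundary signature; shorter clips are aligner noise.
#' @param block_size Block width (bp) used for the block mean coverage
#'   feature; every position in a block shares the block's mean long-read
#'   depth.
#' @param hifi_mode If `TRUE`, short-read features are not computed (rows
#'   7-9 of every feature matrix are zero). Use for highly accurate long
#'   reads where short-read support adds nothing.
#'
#' @return A named list of class `deepdel_config`.
#' @export
deepdel_config <- function(L = 200L, min_mapq = 20L, min_clip = 10L,
                           block_size = 10000000L, hifi_mode = FALSE) {
  stopifnot(L >= 10, min_mapq >= 0, min_clip >= 0, block_size >= 1)
  structure(list(L = as.integer(L), min_mapq = as.integer(min_mapq),
                 min_clip = as.integer(min_clip),
                 block_size = as.integer(block_size),
                 hifi_mode = isTRUE(hifi_mode)),
            class = "deepdel_config")
}

#' Tile a chromosome into consecutive sub-regions
#'
#' Divides `[offset, chrom_length)` into consecutive, non-overlapping tiles
#' of width `L`; the final tile may be shorter. Coordinates are 0-based,
#' half-open. A second tiling at `offset = L/2` gives the shifted grid used
#' by the two-pass prediction scheme.
#'
#' @param chrom_length Chromosome length in bp (> 0).
#' @param L Tile width in bp.
#' @param offset Start of the first tile (0 <= offset < L).
#' @return A data.frame with columns `start`, `end` (0-based, half-open).
#' @export
#' @examples
#' tile_reference(450, 200)          # (0,200) (200,400) (400,450)
#' tile_reference(700, 200, 100)     # (100,300) (300,500) (500,700)
tile_reference <- function(chrom_length, L = 200L, offset = 0L) {
  if (length(chrom_length) != 1L || is.na(chrom_length) || chrom_length <= 0)
    stop("chrom_length must be a single positive number")
  stopifnot(offset >= 0, offset < L)
  starts <- seq.int(offset, chrom_length - 1L, by = L)
  ends <- pmin(starts + L, chrom_length)
  data.frame(start = as.integer(starts), end = as.integer(ends))
}
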