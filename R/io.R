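## On-disk container for feature tensors: a flat little-endian double
## array plus a JSON sidecar describing dimensions and per-tile metadata.

#' Write a feature set to disk
#'
#' Stores a `(9, L, N)` feature array as `<path>.bin` (little-endian
#' doubles, column-major) with a `<path>.json` sidecar recording the
#' dimensions and one record per tile (`chrom`, `start`, `end`, `L`,
#' `label`).
#'
#' @param x Feature array `(9, L, N)`.
#' @param meta Data frame with `chrom`, `start`, `end` and optionally
#'   `label` (one row per tile).
#' @param path Path prefix (no extension).
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(x, meta, path) {
  x <- .as3d(x)
  stopifnot(nrow(meta) == dim(x)[3])
  if (is.null(meta$label)) meta$label <- NA_integer_
  meta$L <- dim(x)[2]
  jsonlite::write_json(list(dims = dim(x), records = meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.double(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a feature set written by [write_feature_set()]
#'
#' @param path Path prefix used when writing.
#' @return List: `x` (9, L, N array), `meta` (data frame).
#' @export
read_feature_set <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dims)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", prod(d), size = 8L, endian = "little")
  dim(x) <- d
  list(x = x, meta = as.data.frame(side$records))
}
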