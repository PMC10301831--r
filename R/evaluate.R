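## Truth matching and precision/recall for scoring call sets against the
## simulator's planted deletions.

#' Match deletion calls against a truth set
#'
#' A call may match a truth record on the same chromosome when their
#' starts differ by at most `max_bp_dist` and the smaller/larger length
#' ratio is at least `min_size_sim`. Matching is one-to-one and greedy by
#' start distance.
#'
#' @param calls Data frame with `chrom`, `start`, `end`.
#' @param truth Data frame with `chrom`, `start`, `end`.
#' @param max_bp_dist Maximum breakpoint distance (default 1000 bp).
#' @param min_size_sim Minimum size similarity (default 0.7).
#' @return List: `precision`, `recall`, `f1`, and `matches` (data frame of
#'   matched `call` / `truth` row indices).
#' @export
evaluate_calls <- function(calls, truth, max_bp_dist = 1000L,
                           min_size_sim = 0.7) {
  nc <- nrow(calls); nt <- nrow(truth)
  pairs <- NULL
  if (nc > 0L && nt > 0L) {
    cand <- expand.grid(call = seq_len(nc), truth = seq_len(nt))
    cand <- cand[calls$chrom[cand$call] == truth$chrom[cand$truth], ,
                 drop = FALSE]
    d <- abs(calls$start[cand$call] - truth$start[cand$truth])
    lc <- calls$end[cand$call] - calls$start[cand$call]
    lt <- truth$end[cand$truth] - truth$start[cand$truth]
    sim <- pmin(lc, lt) / pmax(lc, lt)
    cand <- cand[d <= max_bp_dist & sim >= min_size_sim, , drop = FALSE]
    d <- d[d <= max_bp_dist & sim >= min_size_sim]
    o <- order(d)
    used_c <- logical(nc); used_t <- logical(nt)
    keep <- integer(0)
    for (i in o) {
      ci <- cand$call[i]; ti <- cand$truth[i]
      if (!used_c[ci] && !used_t[ti]) {
        used_c[ci] <- TRUE; used_t[ti] <- TRUE
        keep <- c(keep, i)
      }
    }
    pairs <- cand[keep, , drop = FALSE]
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  precision <- if (nc > 0L) tp / nc else 0
  recall <- if (nt > 0L) tp / nt else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       matches = if (is.null(pairs))
         data.frame(call = integer(0), truth = integer(0)) else pairs)
}
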