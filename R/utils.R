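# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag the top fraction of cells by a score
#'
#' Selects exactly `ceiling(length(score) / 6)` cells (or `n_flag` if given)
#' with the most extreme scores. Ties are broken by ascending cell index, so
#' the selection is deterministic on any input. Cells with `NA` scores or
#' `eligible = FALSE` are never flagged; if fewer eligible cells exist than
#' requested, all eligible cells are flagged with a warning.
#'
#' @param score numeric vector, one value per cell.
#' @param n_flag number of cells to flag; default `ceiling(N/6)`, the
#'   "top 17 percent (1/6)" rule used for hubs, wave initiators and first
#'   responders.
#' @param decreasing if `TRUE` (default) the largest scores are flagged,
#'   otherwise the smallest.
#' @param eligible optional logical mask of cells that may be flagged.
#' @return logical vector of flags.
#' @export
top_fraction_flags <- function(score, n_flag = NULL, decreasing = TRUE,
                               eligible = NULL) {
  n <- length(score)
  if (is.null(n_flag)) n_flag <- ceiling(n / 6)
  if (is.null(eligible)) eligible <- rep(TRUE, n)
  eligible <- eligible & !is.na(score)
  idx <- which(eligible)
  if (length(idx) < n_flag) {
    warning("fewer eligible cells (", length(idx), ") than requested (",
            n_flag, "); flagging all eligible cells")
    n_flag <- length(idx)
  }
  key <- if (decreasing) -score[idx] else score[idx]
  ord <- idx[order(key, idx)]
  flags <- rep(FALSE, n)
  flags[ord[seq_len(n_flag)]] <- TRUE
  flags
}

# Pairwise Euclidean distance matrix from an N x 2 position matrix.
position_dist <- function(positions) {
  as.matrix(stats::dist(positions))
}

# Indices of the k nearest neighbours of every cell (self excluded).
# Returns an N x k integer matrix, row i = neighbours of cell i by distance.
knn_indices <- function(positions, k) {
  d <- position_dist(positions)
  diag(d) <- Inf
  t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
}

# Run-length view of a 0/1 vector: data.frame with columns start, end
# (inclusive frame indices) of each run of ones.
runs_of_ones <- function(states) {
  r <- rle(as.integer(states))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start = starts[keep], end = ends[keep])
}

# Validate a trace_set object; stops with an informative message otherwise.
assert_trace_set <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  dt <- diff(ts$time_s)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (diff(range(dt)) > 1e-6) stop("timestamps must be uniform to 1e-6 s")
  if (!all(is.finite(ts$values))) stop("trace values must be finite")
  if (!all(is.finite(ts$positions))) stop("positions must be finite")
  invisible(ts)
}
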