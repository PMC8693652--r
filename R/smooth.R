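#' Keep genes expressed in at least `min_cells` cells
#'
#' @param counts Raw-layer [sc_counts()].
#' @param min_cells A gene is retained when it has a positive count in at
#'   least this many cells (default 20).
#' @return The reduced [sc_counts()].
#' @export
filter_genes_min_cells <- function(counts, min_cells = 20) {
  keep <- rowSums(unclass(counts) > 0) >= min_cells
  if (!any(keep)) abort("no genes expressed in enough cells",
                        class = "scregnet_validation_error")
  counts[keep, ]
}

#' k-nearest-neighbour smoothing of normalised counts
#'
#' Neighbours are found by Euclidean distance in the top-`n_pcs` PCA space of
#' the log1p-normalised matrix; each cell's smoothed profile is the plain mean
#' of the *normalised* (not log) profiles over itself and its k nearest
#' neighbours. Distance ties are broken by cell index, so the result is fully
#' deterministic. Constant genes are unchanged exactly, and each gene's
#' smoothed values stay within its observed range.
#'
#' @param normalized Normalized-layer [sc_counts()] (counts-per-10k).
#' @param k Number of neighbours (self is added; `k < n_cells`).
#' @param n_pcs PCA dimensions for the neighbour search.
#' @return A smoothed-layer [sc_counts()] with a `provenance` attribute
#'   recording `k` and `n_pcs`.
#' @export
knn_smooth <- function(normalized, k = 10, n_pcs = 30) {
  stopifnot(counts_layer(normalized) %in% c("normalized", "smoothed"))
  if (k <= 0) abort("k must be positive", class = "scregnet_validation_error")
  m <- unclass(normalized)
  n <- ncol(m)
  if (k >= n) abort("k must be smaller than the number of cells",
                    class = "scregnet_validation_error")
  x <- t(log1p(m))
  keep <- apply(x, 2, stats::sd) > 0
  if (any(keep)) {
    x <- scale(x[, keep, drop = FALSE])
    n_pcs <- min(n_pcs, ncol(x), n - 1)
    pc <- stats::prcomp(x, rank. = n_pcs, center = FALSE)$x
  } else {
    pc <- matrix(0, n, 1)
  }
  nn <- knn_index(pc, k)
  sm <- matrix(0, nrow(m), n, dimnames = dimnames(m))
  for (i in seq_len(n)) {
    sm[, i] <- rowMeans(m[, c(i, nn[i, ]), drop = FALSE])
  }
  out <- sc_counts(sm, layer = "smoothed")
  attr(out, "provenance") <- list(k = k, n_pcs = n_pcs)
  out
}
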