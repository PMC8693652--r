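#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_int map_chr
NULL

# Deterministic per-stage seed derived from the master seed, so any stage can
# be rerun in isolation and reproduce its in-pipeline result.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + 1013L * (h %% 1048573L)) %% .Machine$integer.max
}

with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two labelings of the same items, corrected for
#' chance; 1 means identical partitions, 0 is the expected value for
#' independent ones. Used throughout to compare recovered cell classes or
#' gene modules with planted truth.
#'
#' @param a,b Vectors of labels of equal length. Label values are arbitrary.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) return(1)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}

# pairwise Euclidean k nearest neighbours on a small matrix (rows = points);
# ties broken by row index for determinism. Returns integer matrix n x k.
knn_index <- function(x, k) {
  n <- nrow(x)
  if (k >= n) abort("k must be smaller than the number of points")
  d <- as.matrix(stats::dist(x))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))  # secondary key = index: deterministic ties
    ord <- ord[ord != i]
    idx[i, ] <- ord[seq_len(k)]
  }
  idx
}

bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
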