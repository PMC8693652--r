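#' One-way GSEA against a ranked list
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment: walking down the ranked
#' list, hits increment the sum in proportion to `|score|^weight` (normalised
#' over the set) and misses decrement it uniformly; the enrichment score is
#' the extreme deviation (largest in absolute value, signed). The p-value
#' comes from gene-label permutations (random sets of the same size) as the
#' one-way upper tail `P(ES_null >= ES_obs)` with the add-one rule: small p
#' means enrichment at the top of the ranking, depleted sets get p near 1
#' (query the reversed ranking for the other direction). The one-way null
#' keeps the p-values uniform for randomly placed sets.
#'
#' @param ranked Tibble `gene`, `score`, ordered by decreasing score (see
#'   [rank_genes_by_stat()]).
#' @param gene_set Character vector; must intersect the ranked genes.
#' @param n_perm Number of permutations (>= 100).
#' @param weight Exponent on `|score|` for hit increments; 0 gives the
#'   unweighted KS statistic.
#' @param seed Seed for the permutation stream.
#' @return Tibble: `es` in \[-1, 1\], `p`, `n_hits`, `sign`.
#' @export
gsea_oneway <- function(ranked, gene_set, n_perm = 1000, weight = 1,
                        seed = 1L) {
  stopifnot(all(c("gene", "score") %in% names(ranked)))
  if (n_perm < 100) abort("n_perm must be >= 100",
                          class = "scregnet_validation_error")
  genes <- ranked$gene
  scores <- ranked$score
  hits <- genes %in% gene_set
  if (!any(hits)) abort("gene set does not intersect the ranked list",
                        class = "scregnet_validation_error")
  es_obs <- gsea_running_es(scores, hits, weight)
  n_hit <- sum(hits)
  with_stage_seed(seed, "gsea", {
    es_null <- vapply(seq_len(n_perm), function(i) {
      h <- logical(length(genes))
      h[sample(length(genes), n_hit)] <- TRUE
      gsea_running_es(scores, h, weight)
    }, numeric(1))
    tibble(es = es_obs, p = (1 + sum(es_null >= es_obs)) / (n_perm + 1),
           n_hits = n_hit, sign = sign(es_obs))
  })
}

# running-sum ES for a hit indicator over a ranked score vector
gsea_running_es <- function(scores, hits, weight) {
  w <- abs(scores)^weight
  w[hits][w[hits] == 0] <- .Machine$double.eps  # all-zero scores: uniform steps
  inc <- numeric(length(scores))
  inc[hits] <- w[hits] / sum(w[hits])
  n_miss <- sum(!hits)
  if (n_miss > 0) inc[!hits] <- -1 / n_miss
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Hypergeometric over-representation of one set in another
#'
#' Upper-tail hypergeometric p for the overlap of `set_a` and `set_b` within
#' `universe`, plus the fold enrichment (observed / expected overlap).
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes (non-empty).
#' @return Tibble: `overlap`, `expected`, `fold`, `p`.
#' @export
hypergeom_overrepresentation <- function(set_a, set_b, universe) {
  if (length(universe) == 0) abort("empty universe",
                                   class = "scregnet_validation_error")
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("sets must be subsets of the universe",
          class = "scregnet_validation_error")
  }
  a <- unique(set_a); b <- unique(set_b); N <- length(unique(universe))
  ov <- length(intersect(a, b))
  expected <- length(a) * length(b) / N
  tibble(
    overlap = ov,
    expected = expected,
    fold = if (expected > 0) ov / expected else NA_real_,
    p = stats::phyper(ov - 1, length(a), N - length(a), length(b),
                      lower.tail = FALSE)
  )
}

#' Rank genes by signed Wald statistic
#'
#' Adapter from a DE table to the GSEA input: genes ordered by decreasing
#' statistic, ties broken lexicographically by gene id; untested genes
#' (missing statistic) are dropped.
#'
#' @param de A [fit_nb_wald()] table.
#' @return Tibble `gene`, `score`, in rank order.
#' @export
rank_genes_by_stat <- function(de) {
  de %>%
    filter(!is.na(.data$stat)) %>%
    arrange(desc(.data$stat), .data$gene) %>%
    transmute(gene = .data$gene, score = .data$stat)
}
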