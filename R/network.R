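#' Drop genes with minimal variation
#'
#' Removes genes whose coefficient of variation (sd/mean over cells) on the
#' smoothed matrix falls below `min_cv`, the prefilter applied before network
#' inference.
#'
#' @param smoothed Smoothed-layer [sc_counts()].
#' @param min_cv Minimum coefficient of variation.
#' @return The reduced [sc_counts()].
#' @export
prefilter_variable_genes <- function(smoothed, min_cv = 0.05) {
  m <- unclass(smoothed)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  cv <- ifelse(mu > 0, sd / mu, 0)
  keep <- cv >= min_cv
  if (!any(keep)) abort("no genes pass the variability prefilter",
                        class = "scregnet_validation_error")
  smoothed[keep, ]
}

# equal-frequency binning on ranks; ties broken by position for determinism
rank_bins <- function(x, n_bins) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  pmin(pmax(ceiling(r * n_bins / n), 1L), n_bins)
}

default_bins <- function(n) max(2L, as.integer(ceiling(n^(1 / 3))))

# MI in nats from two bin-index vectors
mi_from_bins <- function(bx, by, n_bins, bias_correct = TRUE) {
  n <- length(bx)
  joint <- tabulate(bx + n_bins * (by - 1L), n_bins * n_bins)
  pj <- joint / n
  px <- tabulate(bx, n_bins) / n
  py <- tabulate(by, n_bins) / n
  pp <- outer(px, py)
  pos <- pj > 0
  mi <- sum(pj[pos] * log(pj[pos] / as.vector(pp)[pos]))
  if (bias_correct) {
    kx <- sum(px > 0); ky <- sum(py > 0); kxy <- sum(pos)
    mi <- mi + (kx + ky - kxy - 1) / (2 * n)  # Miller-Madow
  }
  max(mi, 0)
}

#' Mutual information between two expression profiles
#'
#' Rank-based estimator: both vectors are transformed to equal-frequency bins
#' on ranks (`ceiling(n^(1/3))` bins per axis by default), MI is the plug-in
#' estimate from the joint histogram with Miller-Madow bias correction, and
#' the result is floored at zero. Robust to monotone transforms of the inputs.
#'
#' @param x,y Numeric vectors of equal length (>= 30 observations).
#' @param n_bins Bins per axis; `NULL` uses `ceiling(n^(1/3))`.
#' @param bias_correct Apply the Miller-Madow correction (default `TRUE`).
#' @return MI in nats (non-negative).
#' @export
estimate_mi <- function(x, y, n_bins = NULL, bias_correct = TRUE) {
  stopifnot(length(x) == length(y))
  if (length(x) < 30) abort("need >= 30 paired observations",
                            class = "scregnet_validation_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant input vector; MI = 0")
    return(0)
  }
  n_bins <- n_bins %||% default_bins(length(x))
  mi_from_bins(rank_bins(x, n_bins), rank_bins(y, n_bins), n_bins, bias_correct)
}

# MI for every TF x gene pair of a matrix (genes x cells); self pairs get NA.
mi_tf_gene_matrix <- function(m, tfs, n_bins = NULL) {
  n_bins <- n_bins %||% default_bins(ncol(m))
  bins <- t(apply(m, 1, rank_bins, n_bins = n_bins))
  genes <- rownames(m)
  const <- apply(m, 1, stats::sd) == 0
  out <- matrix(NA_real_, length(tfs), length(genes),
                dimnames = list(tfs, genes))
  for (t in tfs) {
    bt <- bins[t, ]
    for (j in seq_along(genes)) {
      if (genes[j] == t) next
      out[t, j] <- if (const[t] || const[j]) 0 else
        mi_from_bins(bt, bins[j, ], n_bins)
    }
  }
  out
}

#' Permutation-null MI cutoff
#'
#' Builds a pooled null by permuting one member of randomly chosen TF-gene
#' pairs and returns the `(1 - alpha)` quantile of the null MI values; with
#' `alpha = 1` the cutoff is the null minimum (every edge kept). Deterministic
#' given `seed`.
#'
#' @param smoothed Smoothed-layer [sc_counts()].
#' @param tfs TF identifiers present in the matrix.
#' @param n_perm Number of permuted pairs (>= 100).
#' @param alpha Significance level; must satisfy `alpha >= 1 / n_perm`.
#' @param n_bins Bins per axis (`NULL` = default rule).
#' @param seed Seed for the permutation stream.
#' @return The MI cutoff (numeric), with the null sample in attribute
#'   `"null"`.
#' @export
mi_threshold_by_permutation <- function(smoothed, tfs, n_perm = 1000,
                                        alpha = 0.05, n_bins = NULL,
                                        seed = 1L) {
  if (n_perm < 100) abort("n_perm must be >= 100",
                          class = "scregnet_validation_error")
  if (alpha < 1 / n_perm) abort("n_perm too small for alpha",
                                class = "scregnet_validation_error")
  m <- unclass(smoothed)
  n_bins <- n_bins %||% default_bins(ncol(m))
  with_stage_seed(seed, "mi_null", {
    null <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      t <- sample(tfs, 1)
      g <- sample(rownames(m), 1)
      bt <- rank_bins(m[t, ], n_bins)
      bg <- rank_bins(sample(m[g, ]), n_bins)
      null[i] <- mi_from_bins(bt, bg, n_bins)
    }
    cutoff <- unname(stats::quantile(null, 1 - alpha, type = 1))
    attr(cutoff, "null") <- null
    cutoff
  })
}

#' Data-processing-inequality pruning
#'
#' For every triangle of edges, the weakest edge `(i, j)` is removed when
#' `MI_ij < min(MI_ik, MI_jk) * (1 - tolerance)`; removals are decided
#' simultaneously on the original MI values, so the result does not depend on
#' edge order. `tolerance = 1` removes nothing.
#'
#' @param edges Tibble with columns `a`, `b`, `mi` (undirected, one row per
#'   edge).
#' @param tolerance DPI tolerance in \[0, 1\].
#' @return The pruned edge tibble.
#' @export
apply_dpi <- function(edges, tolerance = 0.1) {
  if (tolerance < 0 || tolerance > 1) {
    abort("tolerance must lie in [0,1]", class = "scregnet_validation_error")
  }
  if (nrow(edges) == 0) return(edges)
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  tri <- igraph::triangles(g)
  if (length(tri) == 0) return(edges)
  tri <- matrix(as.integer(tri), nrow = 3)
  mi <- edges$mi
  drop <- rep(FALSE, nrow(edges))
  for (i in seq_len(ncol(tri))) {
    v <- tri[, i]
    eids <- igraph::get_edge_ids(g, c(v[1], v[2], v[1], v[3], v[2], v[3]))
    tri_mi <- mi[eids]
    w <- which.min(tri_mi)
    if (tri_mi[w] < min(tri_mi[-w]) * (1 - tolerance)) drop[eids[w]] <- TRUE
  }
  edges[!drop, , drop = FALSE]
}

#' Infer a TF-target network by MI + DPI
#'
#' Computes MI for every TF-gene (and TF-TF) pair on the smoothed matrix,
#' keeps pairs above the permutation-null cutoff, and prunes indirect edges
#' with the data-processing inequality.
#'
#' @inheritParams mi_threshold_by_permutation
#' @param dpi_tolerance DPI tolerance.
#' @return List: `edges` (tibble `a` = TF, `b` = gene, `mi`), `cutoff`,
#'   `mi_tf_tf` (TF x TF MI matrix, for clustering).
#' @export
infer_regulatory_network <- function(smoothed, tfs, n_perm = 1000,
                                     alpha = 0.05, dpi_tolerance = 0.1,
                                     n_bins = NULL, seed = 1L) {
  m <- unclass(smoothed)
  missing_tfs <- setdiff(tfs, rownames(m))
  if (length(missing_tfs) > 0) {
    abort(paste("TFs absent from matrix:", paste(missing_tfs, collapse = ", ")),
          class = "scregnet_validation_error")
  }
  mi <- mi_tf_gene_matrix(m, tfs, n_bins = n_bins)
  cutoff <- mi_threshold_by_permutation(smoothed, tfs, n_perm = n_perm,
                                        alpha = alpha, n_bins = n_bins,
                                        seed = seed)
  hit <- which(!is.na(mi) & mi >= as.numeric(cutoff), arr.ind = TRUE)
  edges <- tibble(a = rownames(mi)[hit[, 1]],
                  b = colnames(mi)[hit[, 2]],
                  mi = mi[hit])
  # TF-TF pairs appear twice (once per direction); keep one canonical copy
  both_tf <- edges$a %in% tfs & edges$b %in% tfs
  canon <- !both_tf | edges$a < edges$b
  edges <- edges[canon, , drop = FALSE] %>% arrange(.data$a, .data$b)
  edges <- apply_dpi(edges, tolerance = dpi_tolerance)
  list(edges = edges, cutoff = as.numeric(cutoff),
       mi_tf_tf = mi[, tfs, drop = FALSE])
}

#' Extract signed regulons from a pruned network
#'
#' Every surviving edge of a TF becomes a target; the sign is the sign of the
#' Spearman correlation between TF and target over cells, and zero-correlation
#' targets are dropped. TFs with no surviving target are retained with an
#' empty regulon (flagged).
#'
#' @param edges Pruned edge tibble (`a` = TF, `b` = target, `mi`), e.g. from
#'   [infer_regulatory_network()].
#' @param smoothed Smoothed-layer [sc_counts()].
#' @param tfs TF catalogue (all present in the matrix).
#' @return A `regulon_set`: tibble `tf`, `target`, `mi`, `rho`, `sign`
#'   (+1/-1), with the empty-regulon TFs in attribute `"empty_tfs"`.
#' @export
build_regulons <- function(edges, smoothed, tfs) {
  m <- unclass(smoothed)
  missing_tfs <- setdiff(tfs, rownames(m))
  if (length(missing_tfs) > 0) {
    abort(paste("TFs absent from matrix:", paste(missing_tfs, collapse = ", ")),
          class = "scregnet_validation_error")
  }
  # re-expand canonical TF-TF edges so each TF owns the other as target
  e1 <- edges %>% filter(.data$a %in% tfs) %>%
    transmute(tf = .data$a, target = .data$b, mi = .data$mi)
  e2 <- edges %>% filter(.data$b %in% tfs & .data$a != .data$b) %>%
    transmute(tf = .data$b, target = .data$a, mi = .data$mi)
  reg <- bind_rows(e1, e2) %>%
    distinct(.data$tf, .data$target, .keep_all = TRUE) %>%
    filter(.data$tf != .data$target)
  if (nrow(reg) > 0) {
    reg$rho <- vapply(seq_len(nrow(reg)), function(i) {
      suppressWarnings(stats::cor(m[reg$tf[i], ], m[reg$target[i], ],
                                  method = "spearman"))
    }, numeric(1))
    reg$rho[is.na(reg$rho)] <- 0
    reg <- reg[reg$rho != 0, , drop = FALSE]
    reg$sign <- sign(reg$rho)
  } else {
    reg$rho <- numeric(0); reg$sign <- numeric(0)
  }
  reg <- reg %>% arrange(.data$tf, .data$target)
  empty <- setdiff(tfs, unique(reg$tf))
  attr(reg, "empty_tfs") <- empty
  class(reg) <- c("regulon_set", class(reg))
  reg
}

#' Two-tailed master-regulator analysis
#'
#' For each TF, tests whether its signed regulon overlaps the disease
#' signature in the activating orientation (positive regulon in the up set,
#' negative regulon in the down set) or the inhibiting orientation (the
#' reverse), by upper-tail hypergeometric tests over the shared universe.
#' FDR is BH over the per-TF stronger tail; a TF is called `activated`
#' (`inhibited`) when that tail is the activation (inhibition) one and the
#' FDR passes `mra_fdr`.
#'
#' @param regulons A [build_regulons()] tibble.
#' @param signature An [extract_signature()] object.
#' @param universe Character vector of genes over which both the regulons and
#'   the signature are defined.
#' @param mra_fdr FDR threshold for a call.
#' @param de Optional [fit_nb_wald()] table; adds `tf_log2fc`, `tf_padj`.
#' @return An `mra_result` tibble: `tf`, regulon sizes, `p_activation`,
#'   `p_inhibition`, `fdr`, `call`, and TF expression columns when `de` is
#'   given.
#' @export
master_regulator_analysis <- function(regulons, signature, universe,
                                      mra_fdr = 0.01, de = NULL) {
  if (length(signature$up) + length(signature$down) == 0) {
    abort("empty signature; master-regulator analysis refused",
          class = "scregnet_validation_error")
  }
  up <- intersect(signature$up, universe)
  down <- intersect(signature$down, universe)
  N <- length(universe)
  K <- length(up) + length(down)
  tfs <- sort(unique(c(regulons$tf, attr(regulons, "empty_tfs"))))
  rows <- lapply(tfs, function(t) {
    sub <- regulons[regulons$tf == t, , drop = FALSE]
    pos <- intersect(sub$target[sub$sign > 0], universe)
    neg <- intersect(sub$target[sub$sign < 0], universe)
    n_draw <- length(pos) + length(neg)
    if (n_draw == 0) {
      return(tibble(tf = t, n_pos = 0L, n_neg = 0L, k_act = 0L, k_inh = 0L,
                    p_activation = 1, p_inhibition = 1))
    }
    k_act <- length(intersect(pos, up)) + length(intersect(neg, down))
    k_inh <- length(intersect(pos, down)) + length(intersect(neg, up))
    tibble(
      tf = t, n_pos = length(pos), n_neg = length(neg),
      k_act = k_act, k_inh = k_inh,
      p_activation = stats::phyper(k_act - 1, K, N - K, n_draw,
                                   lower.tail = FALSE),
      p_inhibition = stats::phyper(k_inh - 1, K, N - K, n_draw,
                                   lower.tail = FALSE)
    )
  })
  out <- bind_rows(rows)
  out$fdr <- bh_adjust(pmin(out$p_activation, out$p_inhibition))
  out$call <- with(out, ifelse(
    fdr < mra_fdr & p_activation < p_inhibition, "activated",
    ifelse(fdr < mra_fdr & p_inhibition < p_activation, "inhibited", "none")
  ))
  out$call[out$n_pos + out$n_neg == 0] <- "none"
  if (!is.null(de)) {
    idx <- match(out$tf, de$gene)
    out$tf_log2fc <- de$log2fc[idx]
    out$tf_padj <- de$padj[idx]
  }
  class(out) <- c("mra_result", class(out))
  out
}

#' Concordance filter: the core master-regulator set
#'
#' Keeps a TF when (1) it is itself differentially expressed
#' (`tf_padj < alpha` and `|tf_log2fc| > lfc`), (2) its regulon association is
#' significant (a non-`"none"` MRA call), and (3) TF and regulon move in the
#' same direction (`activated` requires `tf_log2fc > 0`, `inhibited` requires
#' `tf_log2fc < 0`). TFs absent from the DE table are excluded with a warning.
#'
#' @param mra An [master_regulator_analysis()] result.
#' @param de A [fit_nb_wald()] table covering the TFs.
#' @param alpha,lfc DE thresholds for the TF itself.
#' @return `mra` with `tf_log2fc`, `tf_padj`, `concordant` and
#'   `passes_core_filter` columns; the core set is the
#'   `passes_core_filter` subset.
#' @export
concordance_filter <- function(mra, de, alpha = 0.01, lfc = 1.0) {
  idx <- match(mra$tf, de$gene)
  if (anyNA(idx)) {
    warn(paste("TFs absent from DE table excluded:",
               paste(mra$tf[is.na(idx)], collapse = ", ")))
  }
  mra$tf_log2fc <- de$log2fc[idx]
  mra$tf_padj <- de$padj[idx]
  sig_de <- !is.na(mra$tf_padj) & mra$tf_padj < alpha &
    !is.na(mra$tf_log2fc) & abs(mra$tf_log2fc) > lfc
  mra$concordant <- !is.na(mra$tf_log2fc) &
    ((mra$call == "activated" & mra$tf_log2fc > 0) |
       (mra$call == "inhibited" & mra$tf_log2fc < 0))
  mra$passes_core_filter <- sig_de & mra$call != "none" & mra$concordant
  mra$passes_core_filter[is.na(idx)] <- FALSE
  mra
}

#' Cluster core TFs on mutual information
#'
#' Average-linkage hierarchical clustering of `1 - MI / max(MI)` over the
#' given TFs; high-MI TFs (co-regulated) cluster together.
#'
#' @param mi_tf_tf TF x TF mutual-information matrix.
#' @param tfs TFs to cluster (>= 1).
#' @param k Number of clusters to report.
#' @return List: `hclust` (or `NULL` for a single TF), `clusters` tibble
#'   (`tf`, `cluster`).
#' @export
tf_tf_mi_clustering <- function(mi_tf_tf, tfs, k = 2) {
  tfs <- intersect(tfs, rownames(mi_tf_tf))
  if (length(tfs) == 1) {
    return(list(hclust = NULL, clusters = tibble(tf = tfs, cluster = 1L)))
  }
  mm <- mi_tf_tf[tfs, tfs, drop = FALSE]
  mm[is.na(mm)] <- max(mm, na.rm = TRUE)  # self entries
  top <- max(mm)
  d <- if (top > 0) 1 - mm / top else matrix(0, nrow(mm), ncol(mm),
                                             dimnames = dimnames(mm))
  d <- (d + t(d)) / 2
  if (max(d) < 1e-12) {
    return(list(hclust = NULL,
                clusters = tibble(tf = tfs, cluster = 1L)))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, k = min(k, length(tfs)))
  list(hclust = hc, clusters = tibble(tf = tfs, cluster = as.integer(cl[tfs])))
}

#' Overlap of regulon halves with coexpression modules
#'
#' Upper-tail hypergeometric test of every (TF, regulon half) x module pair
#' over a shared universe, BH-corrected across the whole table.
#'
#' @param regulons A [build_regulons()] tibble.
#' @param modules A [module_set()].
#' @param universe Shared gene universe.
#' @return Tibble `tf`, `half` (`positive` / `negative`), `module`,
#'   `overlap`, `regulon_size`, `module_size`, `p`, `padj`.
#' @export
regulon_module_overlap <- function(regulons, modules, universe) {
  mods <- names(modules$sizes)
  mod_sets <- lapply(mods, function(mm)
    intersect(modules$assignment$gene[modules$assignment$module == mm],
              universe))
  names(mod_sets) <- mods
  N <- length(universe)
  rows <- list()
  for (t in unique(regulons$tf)) {
    sub <- regulons[regulons$tf == t, ]
    halves <- list(positive = intersect(sub$target[sub$sign > 0], universe),
                   negative = intersect(sub$target[sub$sign < 0], universe))
    for (h in names(halves)) {
      rg <- halves[[h]]
      for (mm in mods) {
        ms <- mod_sets[[mm]]
        ov <- length(intersect(rg, ms))
        p <- if (length(ms) == 0 || length(rg) == 0) 1 else
          stats::phyper(ov - 1, length(ms), N - length(ms), length(rg),
                        lower.tail = FALSE)
        rows[[length(rows) + 1]] <- tibble(
          tf = t, half = h, module = mm, overlap = ov,
          regulon_size = length(rg), module_size = length(ms), p = p)
      }
    }
  }
  out <- bind_rows(rows)
  out$padj <- bh_adjust(out$p)
  out
}
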