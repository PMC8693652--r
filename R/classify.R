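#' Per-cell quality-control metrics
#'
#' @param counts Raw-layer [sc_counts()].
#' @param annotation Tibble with at least `cell_id` (one row per cell of
#'   `counts`); QC columns are added.
#' @param mito_prefix Prefix identifying mitochondrial genes (default `"MT-"`).
#' @return `annotation` with `total_counts`, `detected_genes`,
#'   `mito_fraction` filled in.
#' @export
compute_qc_metrics <- function(counts, annotation, mito_prefix = "MT-") {
  stopifnot(counts_layer(counts) == "raw")
  ann <- as_tibble(annotation)
  stopifnot(setequal(ann$cell_id, colnames(counts)))
  m <- unclass(counts)[, ann$cell_id, drop = FALSE]
  tot <- colSums(m)
  mito <- startsWith(rownames(m), mito_prefix)
  if (!any(mito)) {
    warn(paste0("no genes match mito prefix '", mito_prefix,
                "'; mito_fraction set to 0"))
    mfrac <- rep(0, ncol(m))
  } else {
    mfrac <- ifelse(tot == 0, 0, colSums(m[mito, , drop = FALSE]) / tot)
  }
  ann$total_counts <- as.integer(round(tot))
  ann$detected_genes <- as.integer(colSums(m > 0))
  ann$mito_fraction <- unname(mfrac)
  ann
}

#' Filter cells on QC thresholds
#'
#' A cell is retained iff `detected_genes >= min_detected_genes`,
#' `total_counts >= min_total_counts` and
#' `mito_fraction <= max_mito_fraction`.
#'
#' @param annotation Output of [compute_qc_metrics()].
#' @param min_detected_genes,min_total_counts,max_mito_fraction Thresholds.
#' @return `annotation` restricted to retained cells.
#' @export
filter_cells <- function(annotation, min_detected_genes = 1000,
                         min_total_counts = 50000, max_mito_fraction = 0.5) {
  keep <- annotation$detected_genes >= min_detected_genes &
    annotation$total_counts >= min_total_counts &
    annotation$mito_fraction <= max_mito_fraction
  if (!any(keep)) abort("all cells removed by QC filter",
                        class = "scregnet_validation_error")
  annotation[keep, , drop = FALSE]
}

# per-cell panel scores: mean over panel genes of gene-wise z-scored
# log-normalised expression. Rows = cells, columns = panels.
panel_scores <- function(lognorm, panels) {
  m <- unclass(lognorm)
  sapply(panels, function(gs) {
    gs <- intersect(gs, rownames(m))
    if (length(gs) == 0) return(rep(0, ncol(m)))
    sub <- m[gs, , drop = FALSE]
    mu <- rowMeans(sub)
    sd <- apply(sub, 1, stats::sd)
    sd[sd == 0] <- 1
    colMeans((sub - mu) / sd)
  })
}

#' Select a classifier gene set
#'
#' Seeds provisional cell classes by marker-panel scoring (each cell assigned
#' to its argmax panel), tests every gene across those provisional classes
#' with a Kruskal-Wallis test, and returns the union over classes of the
#' `n_top` genes, per class, with the smallest BH-adjusted p among genes whose
#' mean expression is highest in that class.
#'
#' @param lognorm Normalized-layer [sc_counts()] of log1p counts-per-10k.
#' @param panels Named list of marker gene vectors, one per class.
#' @param n_top Genes retained per class.
#' @return Tibble `gene`, `class` (argmax-mean class), `p`, `padj`,
#'   `selected`; the classifier set is `gene[selected]`.
#' @export
select_classifier_genes <- function(lognorm, panels, n_top = 150) {
  scores <- panel_scores(lognorm, panels)
  prov <- colnames(scores)[max.col(scores, ties.method = "first")]
  sizes <- table(prov)
  usable <- names(sizes)[sizes >= 3]
  if (length(usable) < 2) {
    abort("fewer than 2 provisional classes with >= 3 cells",
          class = "scregnet_validation_error")
  }
  if (length(usable) < ncol(scores)) {
    warn(paste("skipping provisional classes with < 3 cells:",
               paste(setdiff(colnames(scores), usable), collapse = ", ")))
  }
  keep_cells <- prov %in% usable
  m <- unclass(lognorm)[, keep_cells, drop = FALSE]
  grp <- factor(prov[keep_cells])
  p <- apply(m, 1, function(v) {
    if (stats::sd(v) == 0) return(1)
    stats::kruskal.test(v, grp)$p.value
  })
  class_means <- sapply(levels(grp), function(k) rowMeans(m[, grp == k, drop = FALSE]))
  res <- tibble(gene = rownames(m),
                class = levels(grp)[max.col(class_means, ties.method = "first")],
                p = unname(p), padj = bh_adjust(p))
  res <- res %>%
    group_by(.data$class) %>%
    mutate(selected = rank(.data$padj, ties.method = "first") <= n_top &
             .data$p < 1) %>%
    ungroup()
  res
}

#' Cluster cells on the classifier gene set
#'
#' Log-normalised expression over the classifier genes is reduced by PCA,
#' a k-nearest-neighbour graph is built in PC space, and communities are
#' found by Leiden modularity optimisation. When `target_clusters` is given,
#' the resolution is calibrated by bisection to reach that cluster count.
#'
#' @param lognorm Normalized-layer [sc_counts()] (log1p cp10k).
#' @param genes Classifier gene set.
#' @param n_pcs Principal components retained.
#' @param k Graph neighbours per cell.
#' @param resolution Leiden resolution (used when `target_clusters` is NULL).
#' @param target_clusters Optional target number of clusters.
#' @param seed Seed for the community search.
#' @return Tibble `cell_id`, `cluster` (integer), plus the 2-D embedding
#'   columns `pc1`, `pc2` for reporting.
#' @export
cluster_cells <- function(lognorm, genes, n_pcs = 30, k = 15,
                          resolution = 1, target_clusters = NULL, seed = 1L) {
  m <- unclass(lognorm)[intersect(genes, rownames(lognorm)), , drop = FALSE]
  n <- ncol(m)
  if (k >= n) abort("cluster_k must be smaller than the number of cells",
                    class = "scregnet_validation_error")
  x <- t(m)
  keep <- apply(x, 2, stats::sd) > 0
  if (!any(keep) || nrow(unique(x)) == 1) {
    warn("all cells identical on classifier genes; single cluster returned")
    return(tibble(cell_id = colnames(m), cluster = 1L, pc1 = 0, pc2 = 0))
  }
  x <- scale(x[, keep, drop = FALSE])
  n_pcs <- min(n_pcs, ncol(x), n - 1)
  pc <- stats::prcomp(x, rank. = n_pcs, center = FALSE, scale. = FALSE)$x
  nn <- knn_index(pc, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  run_leiden <- function(res) {
    with_stage_seed(seed, "leiden", {
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = res, n_iterations = 5)$membership
    })
  }
  if (is.null(target_clusters)) {
    memb <- run_leiden(resolution)
  } else {
    lo <- 1e-4; hi <- 20
    memb <- NULL
    for (i in 1:40) {
      mid <- sqrt(lo * hi)
      memb <- run_leiden(mid)
      nc <- length(unique(memb))
      if (nc == target_clusters) break
      if (nc < target_clusters) lo <- mid else hi <- mid
    }
  }
  # relabel clusters by decreasing size for stable, order-free ids
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  tibble(cell_id = colnames(m),
         cluster = as.integer(relab[as.character(memb)]),
         pc1 = unname(pc[, 1]),
         pc2 = unname(pc[, min(2, ncol(pc))]))
}

#' Label clusters by marker panels
#'
#' Scores each cell against every marker panel (gene-wise z-scored
#' log-normalised expression averaged over the panel), summarises per cluster
#' by the median score, and labels each cluster with its argmax panel. An
#' exact tie yields the label `"unassigned"`.
#'
#' @inheritParams select_classifier_genes
#' @param clusters Tibble `cell_id`, `cluster` from [cluster_cells()].
#' @return Tibble: `cluster`, `size`, one `score_<panel>` column per panel,
#'   `label`.
#' @export
label_clusters <- function(lognorm, clusters, panels) {
  scores <- panel_scores(lognorm[, clusters$cell_id], panels)
  out <- lapply(sort(unique(clusters$cluster)), function(cl) {
    rows <- clusters$cluster == cl
    med <- apply(scores[rows, , drop = FALSE], 2, stats::median)
    best <- which(med == max(med))
    label <- if (length(best) > 1 || all(med == 0)) "unassigned" else names(med)[best]
    c(list(cluster = cl, size = sum(rows)),
      as.list(stats::setNames(med, paste0("score_", names(med)))),
      list(label = label))
  })
  bind_rows(lapply(out, as_tibble))
}

#' Partition clusters into superclusters and flag mixed clusters
#'
#' Cluster centroids (mean log-normalised classifier-gene expression) are
#' correlated, and average-linkage hierarchical clustering of `1 - cor` is cut
#' into `k_super` superclusters. A cluster is flagged *mixed* when its marker
#' label differs from the cell-count-weighted plurality label of its
#' supercluster; mixed clusters are excluded from downstream differential
#' expression. An exact plurality tie flags nothing (with a warning).
#'
#' @inheritParams label_clusters
#' @param genes Classifier gene set used for the centroids.
#' @param labels Output of [label_clusters()].
#' @param k_super Number of superclusters.
#' @return `labels` with `supercluster` and `mixed` columns added.
#' @export
partition_superclusters <- function(lognorm, clusters, genes, labels,
                                    k_super = 3) {
  cl_ids <- sort(unique(clusters$cluster))
  if (length(cl_ids) < 2) abort("need >= 2 clusters for partition analysis",
                                class = "scregnet_validation_error")
  if (k_super > length(cl_ids)) {
    abort("k_super exceeds the number of clusters",
          class = "scregnet_validation_error")
  }
  m <- unclass(lognorm)[intersect(genes, rownames(lognorm)),
                        clusters$cell_id, drop = FALSE]
  cent <- sapply(cl_ids, function(cl)
    rowMeans(m[, clusters$cluster == cl, drop = FALSE]))
  cc <- suppressWarnings(stats::cor(cent))
  cc[is.na(cc)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  super <- stats::cutree(hc, k = k_super)
  out <- labels %>%
    arrange(.data$cluster) %>%
    mutate(supercluster = as.integer(super[match(.data$cluster, cl_ids)]))
  out$mixed <- FALSE
  for (s in unique(out$supercluster)) {
    rows <- which(out$supercluster == s)
    lab <- out$label[rows]
    wt <- tapply(out$size[rows], lab, sum)
    top <- names(wt)[wt == max(wt)]
    if (length(top) > 1) {
      warn(sprintf("supercluster %d has a tied plurality label; no cluster flagged mixed", s))
      next
    }
    out$mixed[rows] <- lab != top
  }
  out
}

#' Percentage of expressing cells for a gene list (HOX code)
#'
#' For each requested gene and each cell group, the percentage of cells with
#' at least one raw count. Genes absent from the matrix are reported with
#' `NA` and `present = FALSE`.
#'
#' @param counts Raw-layer [sc_counts()].
#' @param annotation Tibble with `cell_id` and the grouping column.
#' @param genes Character vector of genes (e.g. the 39 HOX genes).
#' @param group Column of `annotation` to split cells by (default
#'   `"genotype"`).
#' @return Tibble `gene`, `present`, one percentage column per group level.
#' @export
hox_code_matrix <- function(counts, annotation, genes, group = "genotype") {
  ann <- as_tibble(annotation)
  if (nrow(ann) == 0) abort("empty cell set", class = "scregnet_validation_error")
  stopifnot(group %in% names(ann), all(ann$cell_id %in% colnames(counts)))
  m <- unclass(counts)[, ann$cell_id, drop = FALSE]
  lv <- sort(unique(ann[[group]]))
  res <- tibble(gene = genes, present = genes %in% rownames(m))
  for (g in lv) {
    cells <- ann$cell_id[ann[[group]] == g]
    pct <- rep(NA_real_, length(genes))
    hit <- res$present
    pct[hit] <- 100 * rowSums(m[genes[hit], cells, drop = FALSE] > 0) /
      length(cells)
    res[[paste0("pct_", g)]] <- pct
  }
  res
}
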