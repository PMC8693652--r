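#' Signed-hybrid soft-threshold adjacency
#'
#' `a_ij = cor(i, j)^power` when the Pearson correlation over cells is
#' positive, 0 otherwise; the diagonal is 1. Zero-variance genes get zero
#' off-diagonal adjacency with a warning.
#'
#' @param smoothed Smoothed-layer [sc_counts()] (genes x cells).
#' @param power Soft-thresholding power (default 6).
#' @return Gene x gene adjacency matrix in \[0, 1\].
#' @export
adjacency_signed_hybrid <- function(smoothed, power = 6) {
  m <- unclass(smoothed)
  if (ncol(m) < 3) abort("need >= 3 cells", class = "scregnet_validation_error")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("%d zero-variance genes have zero adjacency", sum(sds == 0)))
  }
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[is.na(cc)] <- 0
  a <- ifelse(cc > 0, cc^power, 0)
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k_i = sum_{u != i} a_iu`; the diagonal is 1 and the
#' dissimilarity used for module detection is `1 - TOM`.
#'
#' @param adjacency Symmetric adjacency in \[0, 1\] with unit diagonal.
#' @return The TOM matrix.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  if (!isSymmetric(unname(a), tol = 1e-10)) {
    abort("adjacency must be symmetric", class = "scregnet_validation_error")
  }
  diag(a) <- 1
  l <- a %*% a - 2 * a          # removes u = i and u = j terms (diag = 1)
  k <- rowSums(a) - 1
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# eigengene of one gene set on an expression matrix (genes x cells):
# first principal component of the standardized cell x gene submatrix,
# unit variance, sign aligned with the module mean profile.
eigengene_vector <- function(m, genes) {
  sub <- m[genes, , drop = FALSE]
  if (ncol(sub) < 2) abort("eigengene needs >= 2 cells",
                           class = "scregnet_validation_error")
  x <- t(sub)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  x <- scale(x, scale = sds)
  sv <- svd(x, nu = 1, nv = 0)
  e <- sv$u[, 1]
  if (stats::sd(e) > 0) e <- e / stats::sd(e)
  meanprof <- colMeans(sub)
  if (stats::sd(meanprof) > 0 && stats::cor(e, meanprof) < 0) e <- -e
  stats::setNames(e, colnames(m))
}

#' Module eigengene
#'
#' First principal component of a module's standardized cell x gene
#' submatrix, scaled to unit variance and sign-fixed to correlate positively
#' with the module's mean expression profile.
#'
#' @param smoothed Smoothed-layer [sc_counts()].
#' @param genes Genes of the module.
#' @return Named numeric vector over cells.
#' @export
module_eigengene <- function(smoothed, genes) {
  stopifnot(length(genes) >= 1)
  eigengene_vector(unclass(smoothed), intersect(genes, rownames(smoothed)))
}

#' Cut a TOM dendrogram into modules
#'
#' Average-linkage hierarchical clustering of the dissimilarity, followed by a
#' static height scan: among all merge heights, the one producing the largest
#' number of branches with at least `min_module_size` genes is chosen (ties
#' resolve to the middle of the tied height range, where branches are complete
#' but background genes are not yet absorbed). Genes
#' outside those branches are rescued into the module whose eigengene they
#' correlate with most, when that correlation exceeds `kme_threshold`;
#' otherwise they stay `"unassigned"`.
#'
#' @param dissimilarity Square matrix in \[0, 1\] (1 - TOM) with gene
#'   dimnames.
#' @param min_module_size Minimum genes per module (default 50).
#' @param expr Optional smoothed expression matrix used for the eigengene
#'   rescue step; skipped when `NULL`.
#' @param kme_threshold Minimum eigengene correlation for rescue.
#' @return Tibble `gene`, `module` (`"m1"`, `"m2"`, ... by decreasing size, or
#'   `"unassigned"`).
#' @export
cut_modules <- function(dissimilarity, min_module_size = 50, expr = NULL,
                        kme_threshold = 0.3) {
  d <- dissimilarity
  genes <- rownames(d) %||% paste0("g", seq_len(nrow(d)))
  if (nrow(d) < min_module_size) {
    warn("fewer genes than min_module_size; all unassigned")
    return(tibble(gene = genes, module = "unassigned"))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  heights <- sort(unique(hc$height))
  # the near-top merges glue unrelated background genes together; cutting
  # there yields giant spurious branches, so those heights are not candidates
  low <- heights[heights < 0.99 * max(heights)]
  if (length(low) > 0) heights <- low
  cuts <- stats::cutree(hc, h = heights)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
  n_valid <- apply(cuts, 2, function(cl) sum(table(cl) >= min_module_size))
  best <- which(n_valid == max(n_valid))
  # ties: the lowest tied height gives truncated branches, the highest starts
  # absorbing background; the middle of the tied range takes branches at
  # their natural completion point
  best <- best[ceiling(length(best) / 2)]
  cl <- cuts[, best]
  tab <- table(cl)
  valid <- names(tab)[tab >= min_module_size]
  module <- rep("unassigned", length(genes))
  if (length(valid) > 0) {
    ord <- valid[order(-tab[valid])]
    for (i in seq_along(ord)) module[cl == ord[i]] <- paste0("m", i)
  }
  if (!is.null(expr) && any(module == "unassigned") && length(valid) > 0) {
    m <- unclass(expr)[genes, , drop = FALSE]
    egs <- sapply(unique(module[module != "unassigned"]),
                  function(mm) eigengene_vector(m, genes[module == mm]))
    loose <- which(module == "unassigned")
    v <- m[loose, , drop = FALSE]
    ok <- apply(v, 1, stats::sd) > 0
    if (any(ok)) {
      kme <- suppressWarnings(stats::cor(t(v[ok, , drop = FALSE]), egs))
      kme[is.na(kme)] <- 0
      hit <- apply(kme, 1, max) > kme_threshold
      module[loose[ok][hit]] <-
        colnames(kme)[max.col(kme, ties.method = "first")][hit]
    }
  }
  tibble(gene = genes, module = module)
}

#' Merge modules with correlated eigengenes
#'
#' Eigengenes are clustered (average linkage on `1 - cor`) and the tree cut at
#' height `1 - cutoff`, merging transitively; eigengenes are recomputed and
#' the step repeats until no pair reaches the cutoff.
#'
#' @param smoothed Smoothed-layer [sc_counts()].
#' @param assignment Tibble `gene`, `module` from [cut_modules()].
#' @param cutoff Merge when eigengene correlation >= cutoff (default 0.75).
#' @return A `module_set` (see [module_set()]).
#' @export
merge_similar_modules <- function(smoothed, assignment, cutoff = 0.75) {
  module <- stats::setNames(assignment$module, assignment$gene)
  m <- unclass(smoothed)
  repeat {
    mods <- setdiff(unique(module), "unassigned")
    if (length(mods) < 2) break
    egs <- sapply(mods, function(mm) eigengene_vector(m, names(module)[module == mm]))
    cc <- suppressWarnings(stats::cor(egs))
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
    if (max(cc[upper.tri(cc)]) < cutoff) break
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    grp <- stats::cutree(hc, h = 1 - cutoff)
    module <- ifelse(module == "unassigned", "unassigned",
                     paste0("tmp", grp[module]))
    names(module) <- assignment$gene
  }
  module_set(smoothed, tibble(gene = assignment$gene, module = unname(module)))
}

#' Assemble a module set
#'
#' Renames modules by decreasing size, computes eigengenes, and bundles
#' assignment + eigengenes into a `module_set` object with [tidy()] /
#' [glance()] methods.
#'
#' @param smoothed Smoothed-layer [sc_counts()].
#' @param assignment Tibble `gene`, `module`.
#' @return A `module_set`: list with `assignment` (tibble), `eigengenes`
#'   (cells x modules matrix), `sizes`, and optional `stability`.
#' @export
module_set <- function(smoothed, assignment) {
  mods <- setdiff(unique(assignment$module), "unassigned")
  sizes <- sort(table(assignment$module[assignment$module != "unassigned"]),
                decreasing = TRUE)
  relab <- stats::setNames(paste0("m", seq_along(sizes)), names(sizes))
  assignment$module <- ifelse(assignment$module == "unassigned", "unassigned",
                              relab[assignment$module])
  m <- unclass(smoothed)
  mods <- paste0("m", seq_along(sizes))
  egs <- sapply(mods, function(mm)
    eigengene_vector(m, assignment$gene[assignment$module == mm]))
  if (length(mods) == 0) egs <- matrix(0, ncol(m), 0, dimnames = list(colnames(m), NULL))
  structure(list(assignment = as_tibble(assignment), eigengenes = egs,
                 sizes = stats::setNames(as.integer(sizes), mods),
                 stability = NULL),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d modules (sizes %s), %d unassigned genes\n",
              length(x$sizes),
              paste(x$sizes, collapse = ", "),
              sum(x$assignment$module == "unassigned")))
  invisible(x)
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a binary trait indicator
#' over the cells of a contrast, BH-corrected across modules within each
#' contrast; significance requires `padj < trait_fdr` and `|r| >
#' trait_min_abs_r`.
#'
#' @param modules A [module_set()].
#' @param annotation Tibble with `cell_id` plus the columns named in the
#'   contrasts.
#' @param contrasts Named list; each element is
#'   `list(column = <annotation column>, level = <value scored 1>)`. Cells
#'   whose column value is `NA` are dropped from that contrast.
#' @param trait_fdr,trait_min_abs_r Significance thresholds (defaults 0.01,
#'   0.4).
#' @return Tibble `contrast`, `module`, `r`, `p`, `padj`, `significant`.
#' @export
module_trait_correlation <- function(modules, annotation, contrasts,
                                     trait_fdr = 0.01, trait_min_abs_r = 0.4) {
  egs <- modules$eigengenes
  ann <- as_tibble(annotation)
  out <- lapply(names(contrasts), function(cn) {
    ct <- contrasts[[cn]]
    rows <- match(rownames(egs), ann$cell_id)
    vals <- ann[[ct$column]][rows]
    use <- !is.na(vals)
    if (sum(use) < 3 || length(unique(vals[use])) < 2) {
      abort(sprintf("contrast '%s' has an empty or constant group", cn),
            class = "scregnet_validation_error")
    }
    ind <- as.numeric(vals[use] == ct$level)
    res <- lapply(colnames(egs), function(mm) {
      e <- egs[use, mm]
      if (stats::sd(e) == 0) return(NULL)  # undefined correlation: excluded
      ht <- stats::cor.test(e, ind)
      tibble(contrast = cn, module = mm, r = unname(ht$estimate),
             p = ht$p.value)
    })
    res <- bind_rows(res)
    res$padj <- bh_adjust(res$p)
    res
  })
  out <- bind_rows(out)
  out$significant <- out$padj < trait_fdr & abs(out$r) > trait_min_abs_r
  class(out) <- c("module_trait", class(out))
  out
}

#' Bootstrap stability of modules
#'
#' For each of `B` bootstrap resamples of cells (with replacement), modules
#' are recomputed from scratch (adjacency, TOM, branch cut; the eigengene
#' rescue of loose genes is skipped, since single-gene rescue is noise-driven
#' under resampling and the score should reflect branch reproducibility); a
#' module's score is 100 times the mean, over resamples, of the best Jaccard
#' index between its gene set and any resampled module. Maximum 100;
#' deterministic given the seed.
#'
#' @param smoothed Smoothed-layer [sc_counts()].
#' @param modules A [module_set()].
#' @param B Bootstrap replicates.
#' @param power,min_module_size Parameters reused for the recomputation.
#' @param seed Seed for the resampling stream.
#' @return `modules` with `stability` filled (named vector, one per module).
#' @export
module_stability_bootstrap <- function(smoothed, modules, B = 20, power = 6,
                                       min_module_size = 50, seed = 1L) {
  if (B < 1) abort("B must be >= 1", class = "scregnet_validation_error")
  m <- unclass(smoothed)
  mods <- names(modules$sizes)
  gene_sets <- lapply(mods, function(mm)
    modules$assignment$gene[modules$assignment$module == mm])
  names(gene_sets) <- mods
  jac <- matrix(0, B, length(mods), dimnames = list(NULL, mods))
  with_stage_seed(seed, "stability", {
    for (b in seq_len(B)) {
      idx <- sample(ncol(m), replace = TRUE)
      sub_m <- m[, idx, drop = FALSE]
      colnames(sub_m) <- paste0("bs", seq_along(idx))
      sub <- sc_counts(sub_m, layer = "smoothed")
      adj <- suppressWarnings(adjacency_signed_hybrid(sub, power = power))
      tom <- topological_overlap(adj)
      cut <- suppressWarnings(
        cut_modules(1 - tom, min_module_size = min_module_size)
      )
      bs_sets <- split(cut$gene, cut$module)
      bs_sets <- bs_sets[names(bs_sets) != "unassigned"]
      for (mm in mods) {
        g <- gene_sets[[mm]]
        best <- 0
        for (s in bs_sets) {
          j <- length(intersect(g, s)) / length(union(g, s))
          if (j > best) best <- j
        }
        jac[b, mm] <- best
      }
    }
  })
  modules$stability <- 100 * colMeans(jac)
  modules
}
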