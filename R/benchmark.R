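#' Score a pipeline result against planted simulation truth
#'
#' Benchmarks every stage of a [run_pipeline()] result on a
#' [simulate_regulatory_counts()] draw: adjusted Rand index of the recovered
#' cell classes, hybrid-cluster detection, differential-expression sensitivity
#' and empirical FDR (genes with |true log2FC| >= 1 count as positives, genes
#' with zero true effect as negatives; the ambiguous band in between enters
#' neither denominator), module recovery over planted module genes, the trait
#' correlation of the recovered disease module, and recovery of the planted
#' master TFs in the concordant core set.
#'
#' @param result A `scregnet_result`.
#' @param truth The `truth` element of a simulation.
#' @return A one-row tibble of recovery metrics.
#' @export
evaluate_against_truth <- function(result, truth) {
  ct <- result$cell_table
  tc <- truth$cells$true_class[match(ct$cell_id, truth$cells$cell_id)]
  hyb <- tc == "hybrid"
  cell_class_ari <- adjusted_rand_index(ct$class_label, tc)
  frac_hybrid_mixed <- if (any(hyb)) mean(ct$class_label[hyb] == "mixed") else NA_real_
  frac_pure_mixed <- mean(ct$class_label[!hyb] == "mixed")

  tg <- truth$genes
  called <- c(result$signature$up, result$signature$down)
  strong <- tg$gene_id[abs(tg$true_log2fc) >= 1]
  nulls <- tg$gene_id[tg$true_log2fc == 0]
  de_sensitivity <- mean(strong %in% called)
  de_fdr <- if (length(called) > 0) {
    sum(called %in% nulls) / length(called)
  } else {
    0
  }

  module_ari <- dis_r <- dis_padj <- NA_real_
  dis_significant <- NA
  if (!is.null(result$modules)) {
    asg <- result$modules$assignment
    planted <- tg$gene_id[!is.na(tg$module)]
    common <- intersect(planted, asg$gene)
    module_ari <- adjusted_rand_index(
      tg$module[match(common, tg$gene_id)],
      asg$module[match(common, asg$gene)])
    # recovered disease module = best Jaccard match of the planted one
    g1 <- tg$gene_id[!is.na(tg$module) & tg$module == "mod1"]
    jac <- vapply(names(result$modules$sizes), function(mm) {
      s <- asg$gene[asg$module == mm]
      length(intersect(g1, s)) / length(union(g1, s))
    }, numeric(1))
    if (length(jac) > 0 && !is.null(result$trait)) {
      best <- names(jac)[which.max(jac)]
      tr <- result$trait[result$trait$module == best &
                           grepl("disease", result$trait$contrast), ]
      if (nrow(tr) == 1) {
        dis_r <- tr$r
        dis_padj <- tr$padj
        dis_significant <- tr$significant
      }
    }
  }

  planted_in_core <- false_core <- NA_integer_
  if (!is.null(result$mra)) {
    core <- result$mra[result$mra$passes_core_filter, ]
    pt <- truth$perturbed_tfs
    idx <- match(pt$tf, core$tf)
    planted_in_core <- sum(!is.na(idx) & core$call[idx] == pt$direction)
    false_core <- nrow(core) - sum(pt$tf %in% core$tf)
  }

  tibble(
    cell_class_ari = cell_class_ari,
    frac_hybrid_mixed = frac_hybrid_mixed,
    frac_pure_mixed = frac_pure_mixed,
    de_sensitivity = de_sensitivity,
    de_empirical_fdr = de_fdr,
    module_ari = module_ari,
    disease_module_r = dis_r,
    disease_module_padj = dis_padj,
    disease_module_significant = dis_significant,
    planted_tfs_in_core = planted_in_core,
    false_positive_core_tfs = false_core
  )
}
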