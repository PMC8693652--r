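#' Positive-count ("poscounts") size factors
#'
#' Median-of-ratios size factors that tolerate the pervasive zeros of
#' single-cell counts: each gene's reference is the geometric mean over cells
#' computed from its positive counts only (the log-sum over positive cells
#' divided by the total number of cells); genes with no positive count are
#' excluded. A cell's factor is the median of its count/reference ratios over
#' its positive genes, and factors are rescaled to geometric mean 1.
#'
#' @param counts Raw-layer [sc_counts()] or integer matrix (genes x cells).
#' @return Named numeric vector of size factors, one per cell.
#' @export
estimate_size_factors_poscounts <- function(counts) {
  m <- unclass(counts)
  if (ncol(m) < 2) abort("need >= 2 cells", class = "scregnet_validation_error")
  logg <- log(m)
  logg[!is.finite(logg)] <- NA
  geo <- exp(rowSums(logg, na.rm = TRUE) / ncol(m))
  geo[rowSums(m > 0) == 0] <- 0
  sf <- apply(m, 2, function(x) {
    ok <- x > 0 & geo > 0
    if (!any(ok)) return(NA_real_)
    exp(stats::median(log(x[ok] / geo[ok])))
  })
  if (anyNA(sf)) {
    abort(paste("cells with no positive counts over reference genes:",
                paste(colnames(m)[is.na(sf)], collapse = ", ")),
          class = "scregnet_validation_error")
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

#' Negative-binomial Wald differential expression
#'
#' Disease-vs-control Wald test per gene under a negative-binomial GLM with
#' design `~ batch + genotype`, positive-count size factors, no outlier
#' replacement, fitted means floored at `minmu`, and p-values referred to a t
#' distribution with residual degrees of freedom - the settings recommended
#' for single-cell counts. The model is fitted by DESeq2 with exactly these
#' options. Genes with zero counts in every cell of the tested subset are
#' dropped before testing, so the BH correction runs over tested genes only;
#' no independent filtering or Cook's cutoff is applied.
#'
#' @param counts Raw-layer [sc_counts()] restricted to the cells under test.
#' @param annotation Tibble with `cell_id`, `genotype` (must contain levels
#'   `"disease"` and `"control"`) and `batch`.
#' @param minmu Lower bound on fitted means.
#' @return A `de_result`: tibble `gene`, `base_mean`, `log2fc` (disease vs
#'   control), `se`, `stat`, `p`, `padj`.
#' @export
fit_nb_wald <- function(counts, annotation, minmu = 1e-6) {
  ann <- as_tibble(annotation)
  stopifnot(all(ann$cell_id %in% colnames(counts)))
  m <- unclass(counts)[, ann$cell_id, drop = FALSE]
  storage.mode(m) <- "integer"
  if (!all(c("disease", "control") %in% ann$genotype)) {
    abort("both genotypes must be present", class = "scregnet_validation_error")
  }
  if (length(unique(ann$batch)) > 1 &&
      any(table(ann$batch, ann$genotype) == 0)) {
    abort("batch is confounded with genotype",
          class = "scregnet_validation_error")
  }
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  col <- data.frame(
    batch = factor(ann$batch),
    genotype = factor(ann$genotype, levels = c("control", "disease"))
  )
  design <- if (nlevels(col$batch) > 1) ~ batch + genotype else ~ genotype
  dds <- DESeq2::DESeqDataSetFromMatrix(m, colData = col, design = design)
  dds <- suppressMessages(DESeq2::DESeq(
    dds, test = "Wald", sfType = "poscounts",
    minReplicatesForReplace = Inf, useT = TRUE, minmu = minmu, quiet = TRUE
  ))
  res <- DESeq2::results(dds, contrast = c("genotype", "disease", "control"),
                         cooksCutoff = FALSE, independentFiltering = FALSE)
  out <- tibble(
    gene = rownames(res),
    base_mean = res$baseMean,
    log2fc = res$log2FoldChange,
    se = res$lfcSE,
    stat = res$stat,
    p = res$pvalue,
    padj = res$padj
  )
  structure(out, class = c("de_result", class(out)))
}

#' Extract an up/down disease signature from a DE table
#'
#' Membership is exact: `padj < alpha` and `|log2fc| > min_abs_lfc`. The
#' ranked list orders all tested genes by signed Wald statistic, descending,
#' ties broken by gene id.
#'
#' @param de A [fit_nb_wald()] result.
#' @param alpha Adjusted-p cutoff.
#' @param min_abs_lfc Minimum |log2 fold change| (1 = fold change > 2).
#' @return A `signature` list: `up`, `down` (character vectors), `ranked`
#'   (tibble `gene`, `stat`), `alpha`, `min_abs_lfc`.
#' @export
extract_signature <- function(de, alpha = 0.01, min_abs_lfc = 1.0) {
  ok <- !is.na(de$padj) & !is.na(de$log2fc)
  up <- de$gene[ok & de$padj < alpha & de$log2fc > min_abs_lfc]
  down <- de$gene[ok & de$padj < alpha & de$log2fc < -min_abs_lfc]
  if (length(up) + length(down) == 0) {
    warn("empty signature: no genes pass the thresholds")
  }
  ranked <- de %>%
    filter(!is.na(.data$stat)) %>%
    arrange(desc(.data$stat), .data$gene) %>%
    select("gene", "stat")
  structure(list(up = up, down = down, ranked = as_tibble(ranked),
                 alpha = alpha, min_abs_lfc = min_abs_lfc),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> %d up / %d down (padj < %g, |log2FC| > %g)\n",
              length(x$up), length(x$down), x$alpha, x$min_abs_lfc))
  invisible(x)
}

#' Hypergeometric overlap between two signatures
#'
#' Upper-tail hypergeometric test of the observed overlap per direction,
#' as used to compare up/down gene sets from two differential-expression
#' contrasts over a shared gene universe.
#'
#' @param sig_a,sig_b [extract_signature()] objects.
#' @param universe_size Number of genes tested in both contrasts.
#' @return Tibble with one row per direction: sizes, `overlap`, `p`.
#' @export
signature_overlap_test <- function(sig_a, sig_b, universe_size) {
  res <- lapply(c("up", "down"), function(dir) {
    a <- sig_a[[dir]]; b <- sig_b[[dir]]
    if (universe_size < max(length(a), length(b))) {
      abort("universe smaller than a signature set",
            class = "scregnet_validation_error")
    }
    ov <- length(intersect(a, b))
    tibble(direction = dir, size_a = length(a), size_b = length(b),
           overlap = ov,
           p = stats::phyper(ov - 1, length(a), universe_size - length(a),
                             length(b), lower.tail = FALSE))
  })
  bind_rows(res)
}
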