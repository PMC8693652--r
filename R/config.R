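#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the published
#' defaults where a published value exists: soft-thresholding power 6
#' (signed hybrid), minimum module size 50, eigengene merge cutoff 0.75,
#' module-trait significance at adjusted p < 0.01 and |r| > 0.4, differential
#' expression signature at adjusted p < 0.01 and |log2 fold change| > 1, and
#' gene retention at expression in >= 20 cells. Remaining values (QC cutoffs,
#' smoothing k, MI settings) are declared defaults, all overridable.
#'
#' @param rng_seed Master seed; every stochastic stage draws a named substream
#'   from it.
#' @param min_detected_genes,min_total_counts,max_mito_fraction Cell QC cutoffs.
#' @param knn_k Neighbours used for count smoothing (self is added to the
#'   average).
#' @param n_pcs Principal components for the smoothing / clustering space.
#' @param cluster_k Neighbours for the cell clustering graph.
#' @param resolution Leiden resolution; ignored when `target_clusters` is set.
#' @param target_clusters If non-`NULL`, calibrate the resolution by bisection
#'   to this many clusters. The default of 8 deliberately over-clusters
#'   relative to the number of cell classes: partition analysis can only flag
#'   a mixed sub-population if clustering first isolates it.
#' @param k_super Number of superclusters for partition analysis.
#' @param n_top_classifier Genes kept per provisional class when building the
#'   classifier gene set.
#' @param soft_power Signed-hybrid soft-thresholding power.
#' @param min_module_size Minimum genes per coexpression module.
#' @param merge_cutoff Eigengene correlation at or above which modules merge.
#' @param trait_fdr,trait_min_abs_r Module-trait significance thresholds.
#' @param de_alpha,de_min_abs_lfc Signature thresholds on adjusted p and
#'   |log2 fold change|.
#' @param min_cells_per_gene Gene retention: expressed in at least this many
#'   cells.
#' @param min_cv Coefficient-of-variation prefilter before network inference.
#' @param mi_permutations Permutations for the MI edge-significance null.
#' @param mi_alpha Edge significance level.
#' @param dpi_tolerance Data-processing-inequality tolerance in \[0, 1\].
#' @param mra_fdr FDR cutoff for master-regulator calls.
#' @param bootstrap_reps Cell-bootstrap replicates for module stability.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rng_seed = 1L,
                            min_detected_genes = 1000L,
                            min_total_counts = 50000L,
                            max_mito_fraction = 0.5,
                            knn_k = 10L,
                            n_pcs = 30L,
                            cluster_k = 15L,
                            resolution = 1,
                            target_clusters = 8L,
                            k_super = 3L,
                            n_top_classifier = 150L,
                            soft_power = 6,
                            min_module_size = 50L,
                            merge_cutoff = 0.75,
                            trait_fdr = 0.01,
                            trait_min_abs_r = 0.4,
                            de_alpha = 0.01,
                            de_min_abs_lfc = 1.0,
                            min_cells_per_gene = 20L,
                            min_cv = 0.05,
                            mi_permutations = 1000L,
                            mi_alpha = 0.05,
                            dpi_tolerance = 0.1,
                            mra_fdr = 0.01,
                            bootstrap_reps = 20L) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "scregnet_validation_error")
  chk(cfg$max_mito_fraction >= 0 && cfg$max_mito_fraction <= 1,
      "max_mito_fraction must lie in [0,1]")
  chk(cfg$dpi_tolerance >= 0 && cfg$dpi_tolerance <= 1,
      "dpi_tolerance must lie in [0,1]")
  chk(cfg$knn_k >= 1, "knn_k must be positive")
  chk(cfg$soft_power > 0, "soft_power must be positive")
  chk(cfg$merge_cutoff > 0 && cfg$merge_cutoff <= 1,
      "merge_cutoff must lie in (0,1]")
  for (f in c("trait_fdr", "de_alpha", "mra_fdr", "mi_alpha")) {
    chk(cfg[[f]] > 0 && cfg[[f]] <= 1, paste(f, "must lie in (0,1]"))
  }
  chk(cfg$min_module_size >= 1, "min_module_size must be positive")
  chk(cfg$bootstrap_reps >= 1, "bootstrap_reps must be >= 1")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a [pipeline_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg A [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
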