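run_stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "scregnet_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stage order classify -> differential expression ->
#' smoothing -> coexpression modules -> regulatory network -> master-regulator
#' analysis, on raw counts plus cell metadata, marker panels and a TF
#' catalogue. Deterministic given `config$rng_seed`: every stochastic stage
#' draws a named substream from it.
#'
#' @param counts Raw-layer [sc_counts()].
#' @param annotation Tibble `cell_id`, `genotype`, `batch`.
#' @param panels Named list of marker gene vectors (class name -> genes).
#' @param tf_catalogue Character vector of TF gene ids.
#' @param config A [pipeline_config()].
#' @param hox_genes Optional gene list for the percent-expressing summary.
#' @param de_class Class whose cells enter differential expression (default
#'   `"MN"`).
#' @param analysis_classes Classes whose non-mixed cells enter smoothing,
#'   modules and network inference (default `c("MN", "IN")`).
#' @param stages Subset of `c("modules", "network")` to run after the always-on
#'   classify/DE/smooth stages; both by default.
#' @return A `scregnet_result` list; see the individual stage functions for
#'   the elements.
#' @export
run_pipeline <- function(counts, annotation, panels, tf_catalogue,
                         config = pipeline_config(), hox_genes = NULL,
                         de_class = "MN", analysis_classes = c("MN", "IN"),
                         stages = c("modules", "network")) {
  validate_config(config)
  seed <- config$rng_seed
  if (config$knn_k >= ncol(counts)) {
    abort("knn_k must be smaller than the number of cells",
          class = "scregnet_validation_error")
  }

  ann <- run_stage("qc", {
    qc <- compute_qc_metrics(counts, annotation)
    filter_cells(qc, config$min_detected_genes, config$min_total_counts,
                 config$max_mito_fraction)
  })
  counts_f <- counts[, ann$cell_id]
  lognorm <- normalize_counts(counts_f, log1p = TRUE)

  cls <- run_stage("classify", {
    sel <- select_classifier_genes(lognorm, panels,
                                   n_top = config$n_top_classifier)
    classifier_genes <- sel$gene[sel$selected]
    clusters <- cluster_cells(lognorm, classifier_genes,
                              n_pcs = config$n_pcs, k = config$cluster_k,
                              resolution = config$resolution,
                              target_clusters = config$target_clusters,
                              seed = seed)
    labels <- label_clusters(lognorm, clusters, panels)
    summary <- partition_superclusters(lognorm, clusters, classifier_genes,
                                       labels, k_super = config$k_super)
    list(sel = sel, genes = classifier_genes, clusters = clusters,
         summary = summary)
  })
  cell_table <- cls$clusters %>%
    left_join(cls$summary %>% select("cluster", "label", "supercluster", "mixed"),
              by = "cluster") %>%
    mutate(class_label = ifelse(.data$mixed, "mixed", .data$label)) %>%
    left_join(ann, by = "cell_id")

  hox <- if (!is.null(hox_genes)) {
    run_stage("hox", hox_code_matrix(counts_f, ann, hox_genes))
  }

  de <- run_stage("de", {
    de_cells <- cell_table$cell_id[cell_table$class_label == de_class]
    if (length(de_cells) < 4) abort("too few cells in the DE class")
    fit_nb_wald(counts_f[, de_cells],
                ann[match(de_cells, ann$cell_id), ])
  })
  signature <- extract_signature(de, alpha = config$de_alpha,
                                 min_abs_lfc = config$de_min_abs_lfc)

  sm <- run_stage("smooth", {
    use <- cell_table$cell_id[cell_table$class_label %in% analysis_classes]
    if (length(use) <= config$knn_k) abort("too few cells to smooth")
    kept <- filter_genes_min_cells(counts_f[, use],
                                   min_cells = config$min_cells_per_gene)
    knn_smooth(normalize_counts(kept), k = config$knn_k,
               n_pcs = config$n_pcs)
  })

  modules <- trait <- NULL
  if ("modules" %in% stages) {
    modules <- run_stage("modules", {
      adj <- suppressWarnings(adjacency_signed_hybrid(sm, power = config$soft_power))
      tom <- topological_overlap(adj)
      cut <- cut_modules(1 - tom, min_module_size = config$min_module_size,
                         expr = sm)
      ms <- merge_similar_modules(sm, cut, cutoff = config$merge_cutoff)
      module_stability_bootstrap(sm, ms, B = config$bootstrap_reps,
                                 power = config$soft_power,
                                 min_module_size = config$min_module_size,
                                 seed = seed)
    })
    trait <- run_stage("module_trait", {
      sm_cells <- colnames(sm)
      tab <- cell_table[match(sm_cells, cell_table$cell_id), ]
      ann2 <- tibble(
        cell_id = sm_cells,
        genotype_in_de_class = ifelse(tab$class_label == de_class,
                                      tab$genotype, NA_character_),
        class_in_control = ifelse(tab$genotype == "control",
                                  tab$class_label, NA_character_)
      )
      contrasts <- list()
      contrasts[[paste0("disease_vs_control_", de_class)]] <-
        list(column = "genotype_in_de_class", level = "disease")
      if (length(analysis_classes) > 1) {
        contrasts[[paste0("control_", de_class, "_vs_other")]] <-
          list(column = "class_in_control", level = de_class)
      }
      module_trait_correlation(modules, ann2, contrasts,
                               trait_fdr = config$trait_fdr,
                               trait_min_abs_r = config$trait_min_abs_r)
    })
  }

  network <- regulons <- mra <- tf_clusters <- reg_mod <- NULL
  universe <- NULL
  if ("network" %in% stages) {
    network <- run_stage("network", {
      var_m <- prefilter_variable_genes(sm, min_cv = config$min_cv)
      tfs <- intersect(tf_catalogue, rownames(var_m))
      if (length(tfs) == 0) abort("no TFs left after the variability prefilter")
      infer_regulatory_network(var_m, tfs, n_perm = config$mi_permutations,
                               alpha = config$mi_alpha,
                               dpi_tolerance = config$dpi_tolerance,
                               seed = seed)
    })
    mra_stage <- run_stage("mra", {
      tfs <- rownames(network$mi_tf_tf)
      regs <- build_regulons(network$edges, sm, tfs)
      uni <- intersect(rownames(prefilter_variable_genes(sm, config$min_cv)),
                       de$gene)
      m <- master_regulator_analysis(regs, signature, uni,
                                     mra_fdr = config$mra_fdr)
      list(regulons = regs, universe = uni,
           mra = concordance_filter(m, de, alpha = config$de_alpha,
                                    lfc = config$de_min_abs_lfc))
    })
    regulons <- mra_stage$regulons
    universe <- mra_stage$universe
    mra <- mra_stage$mra
    core <- mra$tf[mra$passes_core_filter]
    if (length(core) >= 1) {
      tf_clusters <- run_stage("tf_clusters",
                               tf_tf_mi_clustering(network$mi_tf_tf, core))
    }
    if (!is.null(modules) && length(modules$sizes) > 0 && nrow(regulons) > 0) {
      reg_mod <- run_stage(
        "regulon_module_overlap",
        regulon_module_overlap(regulons[regulons$tf %in% core, ],
                               modules, universe)
      )
    }
  }

  structure(list(
    config = config, annotation = ann, cell_table = cell_table,
    cluster_summary = cls$summary, classifier_genes = cls$genes,
    hox = hox, de = de, signature = signature, smoothed = sm,
    modules = modules, trait = trait, network = network,
    regulons = regulons, mra = mra,
    core_tfs = if (!is.null(mra)) mra$tf[mra$passes_core_filter],
    tf_clusters = tf_clusters, regulon_module = reg_mod,
    universe = universe
  ), class = "scregnet_result")
}

#' @export
print.scregnet_result <- function(x, ...) {
  cat("<scregnet_result>\n")
  cat(sprintf("  cells retained: %d; clusters: %d (%d mixed)\n",
              nrow(x$cell_table), nrow(x$cluster_summary),
              sum(x$cluster_summary$mixed)))
  cat(sprintf("  signature: %d up / %d down\n",
              length(x$signature$up), length(x$signature$down)))
  if (!is.null(x$modules)) {
    cat(sprintf("  modules: %d\n", length(x$modules$sizes)))
  }
  if (!is.null(x$mra)) {
    cat(sprintf("  core master regulators: %d\n", length(x$core_tfs)))
  }
  invisible(x)
}

# flatten a pipeline result into named tables for writing
result_tables <- function(result) {
  tabs <- list(
    cell_table = result$cell_table,
    cluster_summary = result$cluster_summary,
    de = result$de,
    signature_up = tibble(gene = result$signature$up),
    signature_down = tibble(gene = result$signature$down),
    mra = result$mra
  )
  if (!is.null(result$hox)) tabs$hox <- result$hox
  if (!is.null(result$modules)) {
    tabs$modules <- result$modules$assignment
    tabs$module_stability <- tibble(
      module = names(result$modules$stability %||% numeric()),
      stability = unname(result$modules$stability %||% numeric()))
    tabs$eigengenes <- as_tibble(result$modules$eigengenes, rownames = "cell_id")
    tabs$module_trait <- result$trait
  }
  if (!is.null(result$network)) {
    tabs$network_edges <- result$network$edges
    tabs$regulons <- as_tibble(result$regulons)
  }
  if (!is.null(result$regulon_module)) tabs$regulon_module <- result$regulon_module
  tabs[!vapply(tabs, is.null, logical(1))]
}

#' Write result tables and a manifest
#'
#' Writes every table as a headered TSV under `outdir` plus a
#' `manifest.yaml` listing file names, row counts and the configuration
#' snapshot used (for provenance).
#'
#' @param x A `scregnet_result` or a named list of data frames.
#' @param outdir Output directory (created if missing).
#' @param config Configuration snapshot to embed; taken from `x` when it is a
#'   pipeline result.
#' @return Tibble `file`, `rows` (the manifest), invisibly.
#' @export
write_results <- function(x, outdir, config = NULL) {
  tabs <- if (inherits(x, "scregnet_result")) result_tables(x) else x
  config <- config %||% (if (inherits(x, "scregnet_result")) x$config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) abort(paste("outdir not writable:", outdir))
  manifest <- tibble(file = character(), rows = integer())
  for (nm in names(tabs)) {
    f <- file.path(outdir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(as.data.frame(tabs[[nm]])), f, progress = FALSE)
    manifest <- bind_rows(manifest, tibble(file = basename(f),
                                           rows = nrow(tabs[[nm]])))
  }
  snap <- list(files = stats::setNames(as.list(manifest$rows), manifest$file),
               config = if (!is.null(config)) unclass(config))
  yaml::write_yaml(snap, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
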