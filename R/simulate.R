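#' Generator settings for synthetic regulatory count data
#'
#' Defaults emulate a plate-based (Smart-seq-style) single-cell experiment on
#' iPSC-derived neurons: two genotypes (disease, control) x two batches,
#' ~300 deep-sequenced cells, three cell classes plus a planted hybrid
#' population, negative-binomial counts with log-normal library sizes,
#' planted coexpression modules (one shifted in disease), and signed
#' TF->target regulons in which a small set of perturbed master TFs drives
#' the disease signature. TF activity is the TF's own latent expression
#' driver, so TF mRNA and regulon move concordantly unless `decouple_tfs`
#' switches that off.
#'
#' @param n_cells_per_genotype Cells per genotype (before low-quality spikes).
#' @param n_genes Total genes, including TFs, class programs, modules and
#'   background.
#' @param n_tfs Number of transcription factors (the TF catalogue).
#' @param targets_per_tf Targets drawn per TF from the background pool.
#' @param frac_positive_targets Fraction of positive-sign targets per regulon.
#' @param weight_range Uniform range of absolute regulon effect weights on the
#'   log scale.
#' @param tf_activity_loading Loading of a TF's latent activity on its own
#'   mRNA.
#' @param n_perturbed Number of disease-perturbed master TFs.
#' @param n_perturbed_inhibited How many of those are inhibited (activity
#'   shifted down) rather than activated.
#' @param activity_shift Log-scale activity shift of perturbed TFs in disease
#'   cells.
#' @param decouple_tfs If `TRUE`, perturbed TF mRNA is driven by an
#'   independent unshifted latent, breaking TF/regulon concordance (exercises
#'   the concordance filter's rejection path).
#' @param n_modules,module_size Planted coexpression modules (disjoint genes).
#' @param module_loading_range Uniform range of module loadings (log scale).
#' @param disease_module_shift Latent shift of module 1 in disease cells.
#' @param n_class_genes Class-program genes per cell class.
#' @param n_markers Marker-panel genes emitted per class (the strongest
#'   class-program genes).
#' @param class_effect Log-scale upregulation of a class program in its class.
#' @param class_props Named proportions for classes MN, IN, non-neuronal and
#'   the MN/IN hybrid population.
#' @param hybrid_marker_boost Multiplier on `class_effect` for MN marker genes
#'   in hybrid cells.
#' @param hybrid_in_marker_atten Multiplier on `class_effect` for IN marker
#'   genes in hybrid cells. Hybrids carry the full IN expression program but
#'   with attenuated IN markers, plus the MN marker panel at MN level, so
#'   their marker label (MN) disagrees with their global profile (IN) - the
#'   situation the mixed-cluster flag exists to catch.
#' @param baseline_sdlog Log-normal sd of relative gene abundances.
#' @param libsize_mean,libsize_sdlog Log-normal library-size model.
#' @param dispersion_mean,dispersion_sdlog Log-normal NB dispersion model.
#' @param batch_sd Per-gene log-scale sd of the second batch's offset.
#' @param n_mito,mito_mass_frac Mitochondrial genes (`MT-` prefix) and their
#'   share of the expected library.
#' @param n_hox Background genes given HOX-style names for the HOX-code
#'   summary.
#' @param n_lowq,lowq_libsize Planted low-quality cells and their tiny library
#'   size (they fail the default QC thresholds).
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_cells_per_genotype = 150L,
                       n_genes = 2000L,
                       n_tfs = 50L,
                       targets_per_tf = 30L,
                       frac_positive_targets = 0.7,
                       weight_range = c(0.4, 0.8),
                       tf_activity_loading = 1.0,
                       n_perturbed = 3L,
                       n_perturbed_inhibited = 1L,
                       activity_shift = 2.0,
                       decouple_tfs = FALSE,
                       n_modules = 5L,
                       module_size = 60L,
                       module_loading_range = c(0.5, 0.8),
                       disease_module_shift = 2.0,
                       n_class_genes = 100L,
                       n_markers = 12L,
                       class_effect = log(6),
                       class_props = c(MN = 0.4, IN = 0.3,
                                       `non-neuronal` = 0.2, hybrid = 0.1),
                       hybrid_marker_boost = 1.0,
                       hybrid_in_marker_atten = 0.5,
                       baseline_sdlog = 1.5,
                       libsize_mean = 3e5,
                       libsize_sdlog = 0.3,
                       dispersion_mean = 0.3,
                       dispersion_sdlog = 0.4,
                       batch_sd = 0.1,
                       n_mito = 10L,
                       mito_mass_frac = 0.15,
                       n_hox = 12L,
                       n_lowq = 10L,
                       lowq_libsize = 2000) {
  p <- as.list(environment())
  reserved <- p$n_tfs + 3L * p$n_class_genes + p$n_modules * p$module_size +
    p$n_mito + p$n_hox
  if (reserved >= p$n_genes) {
    abort("gene layout (TFs + class programs + modules + mito + hox) exceeds n_genes",
          class = "scregnet_validation_error")
  }
  if (p$n_perturbed > p$n_tfs || p$n_perturbed_inhibited > p$n_perturbed) {
    abort("perturbed TFs must be a subset of the TF catalogue",
          class = "scregnet_validation_error")
  }
  if (abs(sum(p$class_props) - 1) > 1e-8 ||
      !setequal(names(p$class_props), c("MN", "IN", "non-neuronal", "hybrid"))) {
    abort("class_props must be named MN/IN/non-neuronal/hybrid and sum to 1",
          class = "scregnet_validation_error")
  }
  structure(p, class = "sim_params")
}

# deterministic gene index layout shared by generator and truth tables
sim_gene_layout <- function(p) {
  n <- p$n_genes
  tf <- seq_len(p$n_tfs)
  cls <- split(
    p$n_tfs + seq_len(3L * p$n_class_genes),
    rep(c("MN", "IN", "non-neuronal"), each = p$n_class_genes)
  )
  off <- p$n_tfs + 3L * p$n_class_genes
  mod <- split(off + seq_len(p$n_modules * p$module_size),
               rep(seq_len(p$n_modules), each = p$module_size))
  off <- off + p$n_modules * p$module_size
  mito <- off + seq_len(p$n_mito)
  hox <- off + p$n_mito + seq_len(p$n_hox)
  bg <- setdiff(seq_len(n), c(tf, unlist(cls), unlist(mod), mito))
  ids <- character(n)
  ids[tf] <- sprintf("TF%02d", seq_along(tf))
  for (k in names(cls)) {
    tag <- c(MN = "MN", IN = "IN", `non-neuronal` = "NN")[[k]]
    ids[cls[[k]]] <- sprintf("%sG%03d", tag, seq_along(cls[[k]]))
  }
  for (m in names(mod)) ids[mod[[m]]] <- sprintf("M%sG%03d", m, seq_len(p$module_size))
  ids[mito] <- sprintf("MT-%02d", seq_along(mito))
  hox_names <- paste0("HOX", rep(c("A", "B", "C", "D"), length.out = p$n_hox),
                      rep(seq_len(ceiling(p$n_hox / 4)), each = 4)[seq_len(p$n_hox)])
  ids[hox] <- hox_names
  rest <- setdiff(bg, hox)
  ids[rest] <- sprintf("G%04d", seq_along(rest))
  list(ids = ids, tf = tf, class_genes = cls, module_genes = mod,
       mito = mito, hox = hox,
       target_pool = setdiff(bg, tf))
}

#' Simulate counts with planted regulatory structure
#'
#' Draws gene x cell negative-binomial counts whose log-mean is the sum of a
#' gene baseline, the cell's class program, module latents, signed TF-activity
#' effects, a batch offset and the log library size; disease cells have the
#' perturbed TFs' activities shifted by `activity_shift` and module 1's latent
#' shifted by `disease_module_shift`. Returns the raw counts, a cell
#' annotation table, and a ground-truth bundle for benchmarking every
#' downstream stage.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed; the draw is fully deterministic given it.
#' @return A list with elements `counts` ([sc_counts()] raw layer),
#'   `annotation` (tibble: cell_id, genotype, batch), and `truth` (list:
#'   `cells`, `genes`, `regulons`, `perturbed_tfs`, `marker_panels`,
#'   `tf_catalogue`, `hox_genes`).
#' @export
simulate_regulatory_counts <- function(params = sim_params(), seed = 1L) {
  p <- if (inherits(params, "sim_params")) params else do.call(sim_params, params)
  lay <- sim_gene_layout(p)
  with_stage_seed(seed, "simulate", {
    n_main <- 2L * p$n_cells_per_genotype
    n_cells <- n_main + p$n_lowq
    genotype <- rep(c("disease", "control"), each = p$n_cells_per_genotype)
    # planted low-quality cells, split over genotypes
    genotype <- c(genotype,
                  rep(c("disease", "control"), length.out = p$n_lowq))
    batch <- paste0("b", rep_len(1:2, n_cells))
    cell_id <- sprintf("cell%03d", seq_len(n_cells))

    # classes balanced within genotype so class and genotype are not confounded
    class_of <- character(n_cells)
    for (g in c("disease", "control")) {
      idx <- which(genotype == g)
      k <- length(idx)
      counts_per <- floor(p$class_props * k)
      rem <- k - sum(counts_per)
      counts_per[seq_len(rem)] <- counts_per[seq_len(rem)] + 1
      class_of[idx] <- sample(rep(names(p$class_props), counts_per))
    }

    m <- stats::rlnorm(p$n_genes, 0, p$baseline_sdlog)
    m[lay$mito] <- p$mito_mass_frac / (1 - p$mito_mass_frac) *
      sum(m[-lay$mito]) / length(lay$mito)
    m <- m / sum(m)

    disp <- stats::rlnorm(p$n_genes, log(p$dispersion_mean), p$dispersion_sdlog)
    lib <- stats::rlnorm(n_cells, log(p$libsize_mean), p$libsize_sdlog)
    low_quality <- c(rep(FALSE, n_main), rep(TRUE, p$n_lowq))
    lib[low_quality] <- p$lowq_libsize

    eta <- matrix(log(m), p$n_genes, n_cells)
    is_disease <- genotype == "disease"

    # class programs (hybrids: full IN program + boosted MN markers)
    for (k in c("MN", "IN", "non-neuronal")) {
      eta[lay$class_genes[[k]], class_of == k] <-
        eta[lay$class_genes[[k]], class_of == k] + p$class_effect
    }
    hyb <- class_of == "hybrid"
    if (any(hyb)) {
      in_genes <- lay$class_genes[["IN"]]
      in_markers <- in_genes[seq_len(p$n_markers)]
      in_rest <- setdiff(in_genes, in_markers)
      eta[in_rest, hyb] <- eta[in_rest, hyb] + p$class_effect
      eta[in_markers, hyb] <- eta[in_markers, hyb] +
        p$hybrid_in_marker_atten * p$class_effect
      mn_markers <- lay$class_genes[["MN"]][seq_len(p$n_markers)]
      eta[mn_markers, hyb] <- eta[mn_markers, hyb] +
        p$hybrid_marker_boost * p$class_effect
    }

    # coexpression modules; module 1 carries the disease shift
    mod_load <- list()
    for (mi in seq_len(p$n_modules)) {
      z <- stats::rnorm(n_cells)
      if (mi == 1L) z <- z + p$disease_module_shift * is_disease
      w <- stats::runif(p$module_size, p$module_loading_range[1],
                        p$module_loading_range[2])
      eta[lay$module_genes[[mi]], ] <- eta[lay$module_genes[[mi]], ] +
        outer(w, z)
      mod_load[[mi]] <- w
    }

    # signed regulons driven by per-cell TF activity
    perturbed <- sprintf("TF%02d", seq_len(p$n_perturbed))
    direction <- c(rep("inhibited", p$n_perturbed_inhibited),
                   rep("activated", p$n_perturbed - p$n_perturbed_inhibited))
    names(direction) <- perturbed
    reg <- vector("list", p$n_tfs)
    tf_ids <- lay$ids[lay$tf]
    tf_lfc <- stats::setNames(numeric(p$n_tfs), tf_ids)
    target_lfc <- stats::setNames(numeric(p$n_genes), lay$ids)
    for (t in seq_len(p$n_tfs)) {
      tfid <- tf_ids[t]
      act <- stats::rnorm(n_cells)
      shift <- 0
      if (tfid %in% perturbed) {
        shift <- if (direction[[tfid]] == "activated") p$activity_shift else -p$activity_shift
        act <- act + shift * is_disease
      }
      tgt <- sample(lay$target_pool, p$targets_per_tf)
      sgn <- ifelse(stats::runif(p$targets_per_tf) < p$frac_positive_targets, 1, -1)
      w <- stats::runif(p$targets_per_tf, p$weight_range[1], p$weight_range[2])
      eta[tgt, ] <- eta[tgt, ] + outer(sgn * w, act)
      target_lfc[tgt] <- target_lfc[tgt] + sgn * w * shift / log(2)
      if (tfid %in% perturbed && p$decouple_tfs) {
        eta[lay$tf[t], ] <- eta[lay$tf[t], ] +
          p$tf_activity_loading * stats::rnorm(n_cells)
      } else {
        eta[lay$tf[t], ] <- eta[lay$tf[t], ] + p$tf_activity_loading * act
        tf_lfc[tfid] <- p$tf_activity_loading * shift / log(2)
      }
      reg[[t]] <- tibble(tf = tfid, target = lay$ids[tgt],
                         sign = sgn, weight = w)
    }

    # batch offset (batch 2 vs batch 1)
    b_off <- stats::rnorm(p$n_genes, 0, p$batch_sd)
    eta[, batch == "b2"] <- eta[, batch == "b2"] + b_off

    comp <- exp(eta)
    comp <- sweep(comp, 2, colSums(comp), "/")
    mu <- sweep(comp, 2, lib, "*")
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu),
                     size = rep(1 / disp, times = n_cells)),
      nrow = p$n_genes, dimnames = list(lay$ids, cell_id)
    )

    true_lfc <- target_lfc
    true_lfc[tf_ids] <- true_lfc[tf_ids] + tf_lfc
    true_lfc[lay$module_genes[[1]]] <- true_lfc[lay$module_genes[[1]]] +
      mod_load[[1]] * p$disease_module_shift / log(2)

    module_of <- rep(NA_character_, p$n_genes)
    for (mi in seq_len(p$n_modules)) {
      module_of[lay$module_genes[[mi]]] <- paste0("mod", mi)
    }
    panels <- lapply(lay$class_genes,
                     function(ix) lay$ids[ix[seq_len(p$n_markers)]])

    truth <- list(
      cells = tibble(cell_id, genotype, batch, true_class = class_of,
                     low_quality, library_size = lib),
      genes = tibble(gene_id = lay$ids, is_tf = lay$ids %in% tf_ids,
                     module = module_of, true_log2fc = unname(true_lfc),
                     dispersion = disp),
      regulons = bind_rows(reg),
      perturbed_tfs = tibble(tf = perturbed, direction = unname(direction),
                             shift = p$activity_shift),
      marker_panels = panels,
      tf_catalogue = tf_ids,
      hox_genes = lay$ids[lay$hox]
    )
    list(counts = sc_counts(counts, "raw"),
         annotation = tibble(cell_id, genotype, batch),
         truth = truth)
  })
}

#' Simulate structureless negative-binomial counts
#'
#' Same count model as [simulate_regulatory_counts()] with every effect
#' (class, module, regulon, batch, disease) switched off: i.i.d. NB counts
#' given gene abundances and library sizes. Used for calibration tests.
#'
#' @inheritParams simulate_regulatory_counts
#' @param n_cells,n_genes Dimensions.
#' @param baseline_sdlog,libsize_mean,libsize_sdlog,dispersion Count model; a
#'   single shared `dispersion` so moment checks have a closed form.
#' @return A list with `counts`, `annotation` (alternating genotype labels,
#'   carrying no signal), and `gene_means` (relative abundances).
#' @export
simulate_null_counts <- function(n_cells = 200L, n_genes = 500L,
                                 baseline_sdlog = 1.5,
                                 libsize_mean = 3e5, libsize_sdlog = 0.3,
                                 dispersion = 0.3, seed = 1L) {
  with_stage_seed(seed, "simulate_null", {
    m <- stats::rlnorm(n_genes, 0, baseline_sdlog)
    m <- m / sum(m)
    lib <- stats::rlnorm(n_cells, log(libsize_mean), libsize_sdlog)
    mu <- outer(m, lib)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
      nrow = n_genes,
      dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                      sprintf("cell%03d", seq_len(n_cells)))
    )
    list(counts = sc_counts(counts, "raw"),
         annotation = tibble(cell_id = colnames(counts),
                             genotype = rep_len(c("disease", "control"), n_cells),
                             batch = paste0("b", rep_len(c(1L, 2L, 2L, 1L), n_cells))),
         gene_means = m, library_sizes = lib)
  })
}
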