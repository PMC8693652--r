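test_that("variability prefilter drops flat genes only", {
  m <- matrix(rpois(200, 10) + 1, 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
  m[1, ] <- 5  # constant
  x <- sc_counts(m + 0, "smoothed")
  kept <- prefilter_variable_genes(x, min_cv = 0.01)
  expect_false("g1" %in% rownames(kept))
  expect_identical(rownames(prefilter_variable_genes(x, 0)), rownames(x))
})

test_that("MI estimator matches the Gaussian closed form and the null", {
  set.seed(51)
  # permutation null at n = 1000 stays below 0.02 nats
  null_mi <- replicate(25, estimate_mi(rnorm(1000), rnorm(1000)))
  expect_true(all(null_mi <= 0.02))
  # bivariate Gaussian: MI = -0.5 log(1 - rho^2)
  for (rho in c(0.5, 0.8)) {
    est <- mean(replicate(3, {
      x <- rnorm(5000)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(5000)
      estimate_mi(x, y)
    }))
    expect_lt(abs(est - (-0.5 * log(1 - rho^2))), 0.05)
  }
})

test_that("self-MI without correction is the plug-in entropy of the binning", {
  set.seed(52)
  x <- rnorm(200)
  b <- 6
  r <- rank(x, ties.method = "first")
  bins <- pmin(pmax(ceiling(r * b / length(x)), 1L), b)
  p <- tabulate(bins, b) / length(x)
  expect_equal(estimate_mi(x, x, n_bins = b, bias_correct = FALSE),
               -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-12)
  expect_warning(mi0 <- estimate_mi(rep(1, 50), rnorm(50)), "constant")
  expect_equal(mi0, 0)
  expect_error(estimate_mi(rnorm(10), rnorm(10)),
               class = "scregnet_validation_error")
})

test_that("the permutation MI cutoff is calibrated and deterministic", {
  set.seed(53)
  m <- matrix(rnorm(60 * 300), 60, dimnames = list(sprintf("g%02d", 1:60),
                                                   sprintf("c%03d", 1:300)))
  x <- sc_counts(m - min(m), "smoothed")
  tfs <- sprintf("g%02d", 1:10)
  cut1 <- mi_threshold_by_permutation(x, tfs, n_perm = 500, alpha = 0.05,
                                      seed = 9)
  cut2 <- mi_threshold_by_permutation(x, tfs, n_perm = 500, alpha = 0.05,
                                      seed = 9)
  expect_identical(as.numeric(cut1), as.numeric(cut2))
  # alpha = 1: cutoff at the null minimum, every edge kept
  cut_all <- mi_threshold_by_permutation(x, tfs, n_perm = 500, alpha = 1,
                                         seed = 9)
  expect_equal(as.numeric(cut_all), min(attr(cut_all, "null")))
  # pure noise: the fraction of pairs above the cutoff is about alpha
  mi <- scregnet:::mi_tf_gene_matrix(unclass(x), tfs)
  frac <- mean(mi[!is.na(mi)] >= as.numeric(cut1))
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.12)
  expect_error(mi_threshold_by_permutation(x, tfs, n_perm = 50),
               class = "scregnet_validation_error")
  expect_error(mi_threshold_by_permutation(x, tfs, n_perm = 100, alpha = 1e-4),
               class = "scregnet_validation_error")
})

test_that("DPI removes exactly the rule-specified edges", {
  edges <- tibble::tibble(a = c("A", "B", "A"), b = c("B", "C", "C"),
                          mi = c(0.5, 0.4, 0.1))
  pruned <- apply_dpi(edges, tolerance = 0)
  expect_equal(nrow(pruned), 2)
  expect_false(any(pruned$a == "A" & pruned$b == "C"))
  # tolerance 1 removes nothing
  expect_equal(nrow(apply_dpi(edges, tolerance = 1)), 3)
  expect_error(apply_dpi(edges, tolerance = 2),
               class = "scregnet_validation_error")
  # enumerated triangles agree with direct rule application at any tolerance
  set.seed(54)
  for (i in 1:50) {
    tol <- sample(c(0, 0.1, 0.3, 1), 1)
    mi3 <- stats::setNames(round(runif(3, 0.01, 1), 3),
                           c("A|B", "B|C", "A|C"))
    e <- tibble::tibble(a = c("A", "B", "A"), b = c("B", "C", "C"),
                        mi = unname(mi3))
    kept <- apply_dpi(e, tol)
    expect_setequal(paste(kept$a, kept$b, sep = "|"),
                    dpi_triangle_oracle(mi3, tol))
  }
})

test_that("DPI prunes the indirect edge of a simulated chain", {
  set.seed(55)
  removed <- replicate(40, {
    y <- rnorm(300)
    x <- y + rnorm(300, 0, 0.6)
    z <- y + rnorm(300, 0, 0.6)
    e <- tibble::tibble(
      a = c("x", "y", "x"), b = c("y", "z", "z"),
      mi = c(estimate_mi(x, y), estimate_mi(y, z), estimate_mi(x, z)))
    pruned <- apply_dpi(e, tolerance = 0)
    !any(pruned$a == "x" & pruned$b == "z")
  })
  expect_gte(mean(removed), 0.95)
})

test_that("regulon extraction recovers planted signed targets", {
  p <- sim_params(n_cells_per_genotype = 100L, n_genes = 300L, n_tfs = 5L,
                  targets_per_tf = 20L, n_perturbed = 1L,
                  n_perturbed_inhibited = 0L, n_modules = 1L,
                  module_size = 55L, n_class_genes = 30L, n_markers = 6L,
                  n_lowq = 0L)
  sim <- cached("reg_sim", simulate_regulatory_counts(p, seed = 61))
  sm <- knn_smooth(normalize_counts(filter_genes_min_cells(sim$counts, 20)),
                   k = 10, n_pcs = 20)
  tfs <- intersect(sim$truth$tf_catalogue, rownames(sm))
  net <- infer_regulatory_network(sm, tfs, n_perm = 300, alpha = 0.05,
                                  dpi_tolerance = 0.1, seed = 62)
  reg <- build_regulons(net$edges, sm, tfs)
  truth <- sim$truth$regulons
  recov <- sapply(tfs, function(t) {
    pl <- truth[truth$tf == t, ]
    got <- reg[reg$tf == t, ]
    hit <- merge(pl, got, by = "target")
    expect_gte(mean(sign(hit$sign.x) == sign(hit$sign.y)), 0.9)
    nrow(hit) / nrow(pl)
  })
  # the disease-perturbed activator is recovered nearly in full; baseline
  # (unshifted) TFs are recovered well on average
  expect_gte(recov[["TF01"]], 0.8)
  expect_gte(mean(recov), 0.8)
  expect_true(all(recov >= 0.6))
  expect_error(build_regulons(net$edges, sm, c(tfs, "NOSUCHTF")),
               "NOSUCHTF")
})

test_that("MRA tail tests equal exhaustive enumeration and extreme cases", {
  u <- paste0("g", 1:50)
  sig <- structure(list(up = u[1:8], down = u[9:12]), class = "signature")
  reg <- tibble::tibble(tf = "tf1",
                        target = c(u[1:6], u[30:33]),
                        mi = 1, rho = c(rep(1, 6), rep(-1, 4)),
                        sign = c(rep(1, 6), rep(-1, 4)))
  attr(reg, "empty_tfs") <- character()
  mra <- master_regulator_analysis(reg, sig, u, mra_fdr = 0.05)
  # activation overlap: 6 of the positive regulon in up, 0 neg in down
  expect_equal(mra$k_act, 6L)
  expect_equal(mra$p_activation, hyper_tail_oracle(6, 50, 12, 10),
               tolerance = 1e-12)
  expect_equal(mra$p_inhibition, hyper_tail_oracle(0, 50, 12, 10),
               tolerance = 1e-12)
  expect_equal(mra$call, "activated")
  # a regulon exactly matching the signature: minimal attainable p
  reg2 <- tibble::tibble(tf = "tf2", target = u[1:12], mi = 1,
                         rho = c(rep(1, 8), rep(-1, 4)),
                         sign = c(rep(1, 8), rep(-1, 4)))
  attr(reg2, "empty_tfs") <- character()
  mra2 <- master_regulator_analysis(reg2, sig, u, mra_fdr = 0.05)
  expect_equal(mra2$p_activation, hyper_tail_oracle(12, 50, 12, 12),
               tolerance = 1e-12)
  expect_equal(mra2$call, "activated")
  # disjoint regulon: no call
  reg3 <- tibble::tibble(tf = "tf3", target = u[30:39], mi = 1, rho = 1,
                         sign = 1)
  attr(reg3, "empty_tfs") <- character()
  expect_equal(master_regulator_analysis(reg3, sig, u)$call, "none")
  # empty signature is refused
  empty_sig <- structure(list(up = character(), down = character()),
                         class = "signature")
  expect_error(master_regulator_analysis(reg, empty_sig, u),
               class = "scregnet_validation_error")
})

test_that("the concordance filter keeps exactly the concordant DE TFs", {
  mra <- tibble::tibble(
    tf = c("t1", "t2", "t3", "t4", "t5"),
    call = c("activated", "activated", "inhibited", "activated", "none"))
  de <- tibble::tibble(gene = c("t1", "t2", "t3", "t4"),
                       log2fc = c(2, -2, -1.5, 2),
                       padj = c(1e-4, 1e-4, 1e-4, 0.5))
  expect_warning(out <- concordance_filter(mra, de), "t5")
  expect_equal(out$passes_core_filter, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$concordant[1:3], c(TRUE, FALSE, TRUE))
})

test_that("decoupled TF expression is rejected by the concordance filter", {
  p <- sim_params(n_cells_per_genotype = 100L, n_genes = 300L, n_tfs = 5L,
                  targets_per_tf = 20L, n_perturbed = 1L,
                  n_perturbed_inhibited = 0L, n_modules = 1L,
                  module_size = 55L, n_class_genes = 30L, n_markers = 6L,
                  n_lowq = 0L, decouple_tfs = TRUE)
  sim <- simulate_regulatory_counts(p, seed = 61)
  sm <- knn_smooth(normalize_counts(filter_genes_min_cells(sim$counts, 20)),
                   k = 10, n_pcs = 20)
  de <- fit_nb_wald(sim$counts, sim$annotation)
  sig <- extract_signature(de)
  tfs <- intersect(sim$truth$tf_catalogue, rownames(sm))
  net <- infer_regulatory_network(sm, tfs, n_perm = 300, alpha = 0.05,
                                  dpi_tolerance = 0.1, seed = 62)
  reg <- build_regulons(net$edges, sm, tfs)
  universe <- intersect(rownames(sm), de$gene)
  mra <- master_regulator_analysis(reg, sig, universe)
  out <- concordance_filter(mra, de)
  # the perturbed TF's regulon is detected, but its own mRNA carries no
  # disease signal, so it cannot enter the core set
  expect_false(out$passes_core_filter[out$tf == "TF01"])
})

test_that("TF clustering by MI recovers planted co-regulation groups", {
  mi <- matrix(0.02, 6, 6, dimnames = list(paste0("t", 1:6), paste0("t", 1:6)))
  mi[1:3, 1:3] <- 0.9
  mi[4:6, 4:6] <- 0.9
  diag(mi) <- NA
  cl <- tf_tf_mi_clustering(mi, paste0("t", 1:6), k = 2)
  expect_equal(length(unique(cl$clusters$cluster)), 2)
  expect_equal(length(unique(cl$clusters$cluster[1:3])), 1)
  expect_equal(length(unique(cl$clusters$cluster[4:6])), 1)
  # permutation invariance of TF order
  cl2 <- tf_tf_mi_clustering(mi[c(4, 1, 5, 2, 6, 3), c(4, 1, 5, 2, 6, 3)],
                             paste0("t", c(4, 1, 5, 2, 6, 3)), k = 2)
  merged <- dplyr::inner_join(cl$clusters, cl2$clusters, by = "tf")
  expect_equal(adjusted_rand_index(merged$cluster.x, merged$cluster.y), 1)
  # identical MI rows: a single cluster
  flat <- matrix(0.5, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  expect_equal(unique(tf_tf_mi_clustering(flat, paste0("t", 1:4))$clusters$cluster),
               1L)
  single <- tf_tf_mi_clustering(mi, "t1")
  expect_equal(single$clusters$cluster, 1L)
})

test_that("regulon-module overlap matches the enumeration oracle", {
  u <- paste0("g", 1:20)
  ms <- list(assignment = tibble::tibble(
    gene = u, module = c(rep("m1", 8), rep("m2", 6), rep("unassigned", 6))),
    sizes = c(m1 = 8L, m2 = 6L))
  reg <- tibble::tibble(tf = "tf1", target = c(u[1:5], u[9:10]), mi = 1,
                        rho = c(rep(1, 5), -1, -1),
                        sign = c(rep(1, 5), -1, -1))
  ov <- regulon_module_overlap(reg, ms, u)
  pos_m1 <- ov[ov$half == "positive" & ov$module == "m1", ]
  expect_equal(pos_m1$overlap, 5L)
  expect_equal(pos_m1$p, hyper_tail_oracle(5, 20, 8, 5), tolerance = 1e-12)
  neg_m2 <- ov[ov$half == "negative" & ov$module == "m2", ]
  expect_equal(neg_m2$overlap, 2L)
  expect_equal(neg_m2$p, hyper_tail_oracle(2, 20, 6, 2), tolerance = 1e-12)
  neg_m1 <- ov[ov$half == "negative" & ov$module == "m1", ]
  expect_equal(neg_m1$overlap, 0L)
  expect_equal(neg_m1$p, hyper_tail_oracle(0, 20, 8, 2), tolerance = 1e-12)
  # containment gives the minimal attainable p for its configuration
  expect_equal(pos_m1$p, hyper_tail_oracle(5, 20, 8, 5))
})
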