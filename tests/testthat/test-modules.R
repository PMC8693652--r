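# 3 cells giving an exact Pearson correlation of 0.5 between the two profiles
cor_half_counts <- function() {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(1, 3, 2), g3 = c(3, 2, 1))
  colnames(m) <- c("c1", "c2", "c3")
  sc_counts(m, "smoothed")
}

test_that("signed-hybrid adjacency is cor^power for positive pairs, else 0", {
  a <- adjacency_signed_hybrid(cor_half_counts(), power = 6)
  expect_equal(a["g1", "g2"], 0.5^6)       # = 0.015625
  expect_equal(a["g1", "g3"], 0)           # cor = -1: truncated
  expect_equal(unname(diag(a)), rep(1, 3))
  x <- sc_counts(matrix(c(1, 2, 3, 2, 4, 6, 5, 5, 5), 3, byrow = TRUE,
                        dimnames = list(paste0("g", 1:3), paste0("c", 1:3))),
                 "smoothed")
  expect_warning(a2 <- adjacency_signed_hybrid(x, 6), "zero-variance")
  expect_equal(a2["g1", "g2"], 1)          # perfectly correlated
  expect_equal(unname(a2["g3", c("g1", "g2")]), c(0, 0))
})

test_that("TOM matches hand computation and the triple-loop oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))  # = 0.5
  expect_equal(unname(diag(tom)), rep(1, 3))
  # no edges: zero off-diagonal overlap
  tom0 <- topological_overlap(diag(4))
  expect_true(all(tom0[upper.tri(tom0)] == 0))
  # random adjacency: equals the definition, in [0,1], symmetric
  set.seed(4)
  r <- matrix(runif(16, 0, 0.9), 4); r <- (r + t(r)) / 2; diag(r) <- 1
  tom_r <- topological_overlap(r)
  expect_equal(tom_r, tom_oracle(r), tolerance = 1e-12)
  expect_true(all(tom_r >= 0 & tom_r <= 1))
  expect_true(isSymmetric(tom_r))
  expect_error(topological_overlap(matrix(c(1, 0.2, 0.5, 1), 2)),
               class = "scregnet_validation_error")
})

# expression with two planted correlated blocks over 100 cells + noise genes
block_expr <- function(n_block = 60, n_noise = 80, n_cells = 100, seed = 9,
                       sd_noise = 0.3) {
  set.seed(seed)
  z1 <- rnorm(n_cells); z2 <- rnorm(n_cells)
  m <- rbind(
    t(sapply(seq_len(n_block), function(i) z1 + rnorm(n_cells, 0, sd_noise))),
    t(sapply(seq_len(n_block), function(i) z2 + rnorm(n_cells, 0, sd_noise)))
  )
  if (n_noise > 0) m <- rbind(m, matrix(rnorm(n_noise * n_cells), n_noise))
  m <- m - min(m)
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("c%03d", seq_len(n_cells)))
  sc_counts(m, "smoothed")
}

test_that("module cutting recovers planted blocks and enforces the size floor", {
  x <- block_expr()
  tom <- topological_overlap(adjacency_signed_hybrid(x, 6))
  cut <- cut_modules(1 - tom, min_module_size = 50, expr = x)
  truth <- rep(c("b1", "b2"), each = 60)
  rec <- cut$module[1:120]
  expect_equal(adjusted_rand_index(truth, rec), 1)
  # gene-order permutation gives the same partition
  set.seed(2)
  perm <- sample(nrow(x))
  tom_p <- topological_overlap(adjacency_signed_hybrid(x[perm, ], 6))
  cut_p <- cut_modules(1 - tom_p, min_module_size = 50, expr = x[perm, ])
  expect_equal(adjusted_rand_index(cut$module[perm], cut_p$module), 1)
  # a 49-gene block stays unassigned at min size 50
  x2 <- block_expr(n_block = 60)
  x2 <- x2[c(1:60, 61:109, 121:200), ]  # second block truncated to 49 genes
  tom2 <- topological_overlap(adjacency_signed_hybrid(x2, 6))
  cut2 <- cut_modules(1 - tom2, min_module_size = 50, expr = x2)
  expect_true(all(cut2$module[61:109] == "unassigned"))
  expect_equal(length(unique(cut2$module[1:60])), 1)
  expect_false(cut2$module[1] == "unassigned")
})

test_that("eigengenes are standardized PCs aligned with the module mean", {
  x <- block_expr(n_block = 10, n_noise = 0)
  # one-gene module: the standardized gene itself
  e1 <- module_eigengene(x, "g001")
  g <- unclass(x)["g001", ]
  expect_equal(unname(e1), unname((g - mean(g)) / sd(g)), tolerance = 1e-10)
  # identical genes: proportional to the common profile
  m <- unclass(x)
  m[2, ] <- m[1, ]
  e2 <- module_eigengene(sc_counts(m, "smoothed"), c("g001", "g002"))
  expect_equal(abs(cor(e2, m[1, ])), 1, tolerance = 1e-10)
  # PC optimality: no random unit combination explains more variance
  genes <- sprintf("g%03d", 1:10)
  e <- module_eigengene(x, genes)
  sub <- scale(t(unclass(x)[genes, ]))
  proj_var <- function(w) var(as.vector(sub %*% (w / sqrt(sum(w^2)))))
  set.seed(12)
  rand <- replicate(200, proj_var(rnorm(10)))
  w_e <- svd(sub, nu = 0, nv = 1)$v[, 1]
  expect_true(all(proj_var(w_e) >= rand - 1e-10))
})

test_that("module merging respects the eigengene-correlation cutoff", {
  x <- block_expr(sd_noise = 0.2)
  assign1 <- tibble::tibble(
    gene = rownames(x),
    module = c(rep("a", 30), rep("b", 30), rep("c", 60),
               rep("unassigned", 80)))
  # a and b are halves of the same planted block: eigengene cor ~ 1 -> merged
  ms <- merge_similar_modules(x, assign1, cutoff = 0.75)
  expect_equal(length(ms$sizes), 2)
  expect_equal(unname(sort(ms$sizes, decreasing = TRUE)), c(60L, 60L))
  # boundary semantics: cutoff just above the observed correlation -> no merge
  e_a <- module_eigengene(x, rownames(x)[1:30])
  e_c <- module_eigengene(x, rownames(x)[61:120])
  r_ac <- cor(e_a, e_c)
  assign2 <- tibble::tibble(gene = rownames(x),
                            module = c(rep("a", 30), rep("unassigned", 30),
                                       rep("c", 60), rep("unassigned", 80)))
  no_merge <- merge_similar_modules(x, assign2, cutoff = min(abs(r_ac) + 0.01, 1))
  expect_equal(length(no_merge$sizes), 2)
  # fixed point: after merging, every pairwise eigengene correlation < cutoff
  egs <- ms$eigengenes
  cc <- cor(egs)
  expect_true(all(cc[upper.tri(cc)] < 0.75))
})

test_that("module-trait correlation flags the planted association", {
  x <- block_expr()
  trait <- as.numeric(unclass(x)["g001", ] > median(unclass(x)["g001", ]))
  ann <- tibble::tibble(cell_id = colnames(x),
                        grp = ifelse(trait == 1, "hi", "lo"))
  ms <- module_set(x, tibble::tibble(
    gene = rownames(x),
    module = c(rep("b1", 60), rep("b2", 60), rep("unassigned", 80))))
  tr <- module_trait_correlation(ms, ann, list(hi = list(column = "grp",
                                                         level = "hi")))
  # exactly the block containing g001 tracks the trait
  expect_equal(sum(tr$significant), 1)
  expect_equal(tr$module[tr$significant], tr$module[which.max(abs(tr$r))])
  # eigengene equal to the indicator: r = 1 exactly
  ind <- rep(c(5, 1), each = 50)
  m_ind <- rbind(gi = ind + 0)
  colnames(m_ind) <- colnames(x)
  ms2 <- module_set(sc_counts(m_ind, "smoothed"),
                    tibble::tibble(gene = "gi", module = "m1"))
  ann2 <- tibble::tibble(cell_id = colnames(x),
                         grp = rep(c("hi", "lo"), each = 50))
  tr2 <- module_trait_correlation(ms2, ann2,
                                  list(hi = list(column = "grp", level = "hi")))
  expect_equal(tr2$r, 1, tolerance = 1e-10)
})

test_that("permuted traits are called significant at about the FDR level", {
  x <- block_expr(n_block = 55, n_noise = 30, seed = 13)
  ms <- module_set(x, tibble::tibble(
    gene = rownames(x),
    module = c(rep("b1", 55), rep("b2", 55), rep("unassigned", 30))))
  set.seed(31)
  hits <- replicate(150, {
    ann <- tibble::tibble(cell_id = colnames(x),
                          grp = sample(rep(c("a", "b"), each = 50)))
    tr <- module_trait_correlation(ms, ann,
                                   list(k = list(column = "grp", level = "a")),
                                   trait_fdr = 0.05, trait_min_abs_r = 0)
    any(tr$significant)
  })
  expect_lt(mean(hits), 0.15)
})

test_that("bootstrap stability separates real from pseudo modules", {
  x <- block_expr(sd_noise = 0.2)
  real <- module_set(x, tibble::tibble(
    gene = rownames(x),
    module = c(rep("b1", 60), rep("b2", 60), rep("unassigned", 80))))
  scored <- module_stability_bootstrap(x, real, B = 10, min_module_size = 50,
                                       seed = 5)
  expect_true(all(scored$stability >= 95))
  # i.i.d. noise genes forced into pseudo-modules score near the random
  # Jaccard baseline
  set.seed(6)
  noise <- matrix(rnorm(140 * 100), 140,
                  dimnames = list(sprintf("n%03d", 1:140),
                                  sprintf("c%03d", 1:100)))
  fake <- module_set(sc_counts(noise - min(noise), "smoothed"),
                     tibble::tibble(gene = rownames(noise),
                                    module = rep(c("f1", "f2"), each = 70)))
  fake_scored <- module_stability_bootstrap(
    sc_counts(noise - min(noise), "smoothed"), fake, B = 10,
    min_module_size = 50, seed = 5)
  expect_true(all(fake_scored$stability < 60))
  # determinism
  again <- module_stability_bootstrap(x, real, B = 10, min_module_size = 50,
                                      seed = 5)
  expect_identical(scored$stability, again$stability)
  expect_error(module_stability_bootstrap(x, real, B = 0),
               class = "scregnet_validation_error")
})
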