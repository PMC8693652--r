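# Shared fixtures (built once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small but fully structured simulation for unit tests; QC thresholds are
# scaled to its 400-gene size wherever cells are filtered
tiny_params <- function(...) {
  defaults <- list(n_cells_per_genotype = 60L, n_genes = 400L, n_tfs = 8L,
                   targets_per_tf = 15L, n_modules = 2L, module_size = 55L,
                   n_class_genes = 40L, n_markers = 8L, n_mito = 5L,
                   n_hox = 6L, n_lowq = 4L)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

tiny_sim <- function() cached("tiny_sim", simulate_regulatory_counts(tiny_params(), seed = 11))

tiny_filter <- function(qc) filter_cells(qc, min_detected_genes = 100,
                                         min_total_counts = 10000,
                                         max_mito_fraction = 0.5)

tiny_lognorm <- function() {
  cached("tiny_lognorm", {
    sim <- tiny_sim()
    ann <- tiny_filter(compute_qc_metrics(sim$counts, sim$annotation))
    list(ann = ann,
         lognorm = normalize_counts(sim$counts[, ann$cell_id], log1p = TRUE))
  })
}

# counts matrix with exactly two well-separated cell populations
two_group_counts <- function(n_per = 30, n_genes = 60, seed = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * 2 * n_per, 20), n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("c%02d", 1:(2 * n_per))))
  m[1:15, 1:n_per] <- m[1:15, 1:n_per] + 200          # program A
  m[16:30, n_per + 1:n_per] <- m[16:30, n_per + 1:n_per] + 200  # program B
  sc_counts(m, "raw")
}

# ---- independent oracles ------------------------------------------------

# upper-tail hypergeometric P(X >= x) by direct tail summation over choose()
hyper_tail_oracle <- function(x, N, K, n) {
  kk <- max(x, max(0, n - (N - K))):min(K, n)
  if (x > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# TOM by direct triple loop over the definition
tom_oracle <- function(a) {
  p <- nrow(a)
  diag(a) <- 1
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(p)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  out
}

# brute-force weighted KS running-sum enrichment score
gsea_es_oracle <- function(scores, hit, weight) {
  n <- length(scores)
  nh <- sum(hit)
  wsum <- sum(abs(scores[hit])^weight)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      w <- abs(scores[i])^weight
      if (wsum == 0) run <- run + 1 / nh else run <- run + w / wsum
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# direct application of the DPI rule to a single triangle: returns the names
# of surviving edges; edges = named vector of the three MI values
dpi_triangle_oracle <- function(mi3, tolerance) {
  drop <- character()
  for (e in names(mi3)) {
    others <- mi3[setdiff(names(mi3), e)]
    if (mi3[[e]] < min(others) * (1 - tolerance)) drop <- c(drop, e)
  }
  setdiff(names(mi3), drop)
}

# poscounts size factors straight from the definition
poscounts_oracle <- function(m) {
  geo <- apply(m, 1, function(x) {
    if (all(x == 0)) return(0)
    exp(sum(log(x[x > 0])) / length(x))
  })
  sf <- apply(m, 2, function(x) {
    ok <- x > 0 & geo > 0
    exp(median(log(x[ok] / geo[ok])))
  })
  sf / exp(mean(log(sf)))
}
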