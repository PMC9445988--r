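# shared fixtures, built in code and cached per test run

.fixture_cache <- new.env(parent = emptyenv())

# simulate + log2 + per-tissue merge/adjust + cross-tissue combine
bundle_fixture <- function(seed = 1) {
  key <- paste0("bundle_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sim <- simulate_study(sim_config(seed = seed))
  datasets <- lapply(sim$datasets, log2_normalise)
  tis <- vapply(datasets, function(d) d$samples$tissue[1], character(1))
  merged <- list()
  for (t in unique(tis)) {
    merged[[t]] <- remove_batch_effects(merge_tissue(datasets[tis == t],
                                                     case_only = TRUE))
  }
  combined <- combine_tissues(merged)
  out <- list(sim = sim, datasets = datasets, dataset_tissue = tis,
              merged = merged, combined = combined)
  .fixture_cache[[key]] <- out
  out
}

# brute-force topological overlap: the O(n^3) triple loop straight from the
# definition, independent of the matrix-product implementation
tom_loop <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# random symmetric adjacency with unit diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# minimal two-group expression dataset from a matrix
quick_ds <- function(expr, status = NULL, tissue = "PFC", batch = "b1") {
  if (is.null(colnames(expr))) colnames(expr) <- sprintf("s%02d", seq_len(ncol(expr)))
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("g%02d", seq_len(nrow(expr)))
  if (is.null(status)) {
    status <- rep(c("case", "control"), length.out = ncol(expr))
  }
  expression_dataset(expr, data.frame(sample_id = colnames(expr),
                                      tissue = tissue, status = status,
                                      batch = batch,
                                      stringsAsFactors = FALSE))
}

# exact CDF of the k-th order statistic of n uniforms, via the binomial sum --
# an oracle independent of pbeta
order_stat_cdf <- function(x, k, n) {
  j <- k:n
  sum(choose(n, j) * x^j * (1 - x)^(n - j))
}
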