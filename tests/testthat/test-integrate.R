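test_that("same-tissue merging concatenates cases over the DEG union", {
  set.seed(2)
  mk <- function(genes, n_case, n_ctrl, batch) {
    x <- matrix(rnorm(length(genes) * (n_case + n_ctrl)), length(genes),
                dimnames = list(genes, sprintf("%s_s%02d", batch,
                                               seq_len(n_case + n_ctrl))))
    quick_ds(x, status = rep(c("case", "control"), c(n_case, n_ctrl)),
             batch = batch)
  }
  genes <- sprintf("g%03d", 1:100)
  d1 <- mk(genes, 10, 5, "b1")
  d2 <- mk(genes, 12, 5, "b2")
  m <- merge_tissue(list(d1, d2), list(genes, genes), case_only = TRUE)
  expect_equal(dim(m$expr), c(100L, 22L))
  expect_equal(as.vector(table(m$samples$batch)[c("b1", "b2")]), c(10L, 12L))

  d3 <- mk(c("A", "B", "C"), 3, 2, "b1")
  d4 <- mk(c("A", "B", "C", "D"), 3, 2, "b2")
  m2 <- merge_tissue(list(d3, d4), list(c("A", "B", "C"), c("B", "C", "D")))
  expect_setequal(rownames(m2$expr), c("A", "B", "C"))  # union, measured in both

  single <- merge_tissue(list(d1), list(genes))
  expect_equal(unique(single$samples$batch), "b1")
  expect_identical(single$expr, d1$expr[, d1$samples$status == "case"])

  expect_error(merge_tissue(list(d3, d4), list("Z", "Q")), "intersection")
})

test_that("batch model is the identity for a single batch", {
  set.seed(4)
  ds <- quick_ds(matrix(rnorm(200), 20), batch = "b1")
  model <- fit_batch_model(ds)
  expect_equal(unname(model$gamma_star[1, ]), rep(0, 20))
  expect_equal(unname(model$delta_star[1, ]), rep(1, 20))
  expect_identical(apply_batch_model(ds, model)$expr, ds$expr)
})

test_that("a pure additive shift is estimated as the +/- c/2 pattern and removed exactly", {
  set.seed(6)
  nb <- 12; ng <- 60; c_shift <- 2.5
  pattern <- rnorm(nb)                  # identical per-sample signal for all genes
  base <- outer(rnorm(ng, 8, 2), rep(1, nb)) + outer(rep(1, ng), pattern)
  x <- cbind(base, base + c_shift)      # batch 2 = batch 1 + c, paired
  dimnames(x) <- list(sprintf("g%02d", 1:ng), sprintf("s%02d", 1:(2 * nb)))
  ds <- quick_ds(x, batch = rep(c("b1", "b2"), each = nb))

  model <- fit_batch_model(ds)
  gamma_orig <- model$gamma_star * rep(sqrt(model$var_pooled), each = 2)
  expect_lt(max(abs(gamma_orig[1, ] + c_shift / 2)), 1e-6)
  expect_lt(max(abs(gamma_orig[2, ] - c_shift / 2)), 1e-6)

  adj <- apply_batch_model(ds, model)
  b1 <- ds$samples$batch == "b1"
  expect_lt(max(abs(rowMeans(adj$expr[, b1]) - rowMeans(adj$expr[, !b1]))), 1e-6)

  # removal is idempotent: re-fitting on adjusted data finds nothing
  refit <- fit_batch_model(adj)
  expect_lt(max(abs(refit$gamma_star)), 1e-6)

  # grand mean per gene preserved
  expect_lt(max(abs(rowMeans(adj$expr) - rowMeans(ds$expr))), 1e-8)
})

test_that("a planted location/scale effect is removed exactly in the noise-free limit", {
  set.seed(7)
  n1 <- 10; n2 <- 12; ng <- 60
  pattern <- rnorm(n1 + n2)
  x <- outer(rnorm(ng, 8, 2), rep(1, n1 + n2)) + outer(rep(1, ng), pattern)
  x[, (n1 + 1):(n1 + n2)] <- x[, (n1 + 1):(n1 + n2)] * 1.6 + 2.5
  dimnames(x) <- list(sprintf("g%02d", 1:ng), sprintf("s%02d", 1:(n1 + n2)))
  ds <- quick_ds(x, batch = rep(c("b1", "b2"), c(n1, n2)))
  adj <- apply_batch_model(ds, fit_batch_model(ds))
  b1 <- ds$samples$batch == "b1"
  expect_lt(max(abs(rowMeans(adj$expr[, b1]) - rowMeans(adj$expr[, !b1]))), 1e-6)
  sd1 <- apply(adj$expr[, b1], 1, sd); sd2 <- apply(adj$expr[, !b1], 1, sd)
  expect_lt(max(abs(sd1 - sd2)), 1e-6)
  expect_lt(max(abs(rowMeans(adj$expr) - rowMeans(ds$expr))), 1e-8)
})

test_that("EB adjustment agrees with the reference ComBat implementation", {
  bf <- bundle_fixture(1)
  tis <- bf$dataset_tissue
  m <- merge_tissue(bf$datasets[tis == "CRE"], case_only = TRUE)
  ours <- remove_batch_effects(m)
  theirs <- suppressMessages(sva::ComBat(m$expr, batch = m$samples$batch))
  expect_lt(max(abs(ours$expr - theirs)), 1e-8)
})

test_that("adjustment shrinks batch structure on the stochastic bundle", {
  bf <- bundle_fixture(1)
  tis <- bf$dataset_tissue
  m <- merge_tissue(bf$datasets[tis == "PFC"], case_only = TRUE)
  adj <- remove_batch_effects(m)
  truth <- bf$sim$truth
  clean <- log2(2^do.call(cbind, truth$clean[tis == "PFC"])[, colnames(m$expr)] + 1)
  clean <- clean[rownames(m$expr), ]
  batch <- m$samples$batch
  batch_means <- function(a) {
    vapply(unique(batch), function(b) rowMeans(a[, batch == b, drop = FALSE]),
           numeric(nrow(a)))
  }
  rmse_before <- sqrt(mean((batch_means(m$expr) - batch_means(clean))^2))
  rmse_after <- sqrt(mean((batch_means(adj$expr) - batch_means(clean))^2))
  expect_lte(rmse_after, 0.5 * rmse_before)

  f_before <- tissuemod:::row_anova_f(m$expr, batch)
  f_after <- tissuemod:::row_anova_f(adj$expr, batch)
  expect_lt(median(f_after, na.rm = TRUE), median(f_before, na.rm = TRUE))

  # no blow-up: adjusted values stay inside a generous envelope of the input
  s <- sd(m$expr)
  expect_true(all(adj$expr >= min(m$expr) - 5 * s & adj$expr <= max(m$expr) + 5 * s))
  # gene and sample order preserved
  expect_identical(dimnames(adj$expr), dimnames(m$expr))
})

test_that("single-sample batches and unknown labels raise errors", {
  set.seed(8)
  ds <- quick_ds(matrix(rnorm(60), 10), batch = c(rep("b1", 5), "b2"))
  expect_error(fit_batch_model(ds), "single sample")
  ds2 <- quick_ds(matrix(rnorm(60), 10), batch = rep(c("b1", "b2"), 3))
  model <- fit_batch_model(ds2)
  ds3 <- ds2; ds3$samples$batch <- rep(c("b1", "b9"), 3)
  expect_error(apply_batch_model(ds3, model), "absent from model")
})

test_that("diagnostics report per-sample spread plus batch-F summaries", {
  bf <- bundle_fixture(1)
  tis <- bf$dataset_tissue
  m <- merge_tissue(bf$datasets[tis == "WB"], case_only = TRUE)
  adj <- remove_batch_effects(m)
  diag_ <- batch_diagnostics(m, adj)
  expect_equal(nrow(diag_), ncol(m$expr) + 2)

  # identical inputs give zero deltas
  same <- batch_diagnostics(m, m)
  expect_equal(same$median_before, same$median_after)
  expect_equal(same$iqr_before[same$row_type == "sample"],
               same$iqr_after[same$row_type == "sample"])

  # per-sample median spread tightens after adjustment
  sm <- diag_[diag_$row_type == "sample", ]
  expect_lt(sd(sm$median_after), sd(sm$median_before))
})
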