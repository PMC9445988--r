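test_that("matrix-product TOM equals the triple-loop definition", {
  for (seed in 1:10) {
    n <- sample(20:30, 1)
    a <- random_adjacency(n, seed)
    expect_lt(max(abs(tom_from_adjacency(a) - tom_loop(a))), 1e-12)
  }
})

test_that("TOM handles the textbook special cases", {
  # isolated pair: a_12 = 1, everything else disconnected
  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 1
  expect_equal(tom_from_adjacency(a)[1, 2], 1)

  # perfectly coupled pair sharing every neighbour: overlap 1
  b <- diag(4)
  b[1, 2] <- b[2, 1] <- 1              # identical genes
  b[1, 3] <- b[3, 1] <- b[2, 3] <- b[3, 2] <- 1
  b[1, 4] <- b[4, 1] <- b[2, 4] <- b[4, 2] <- 1
  expect_equal(tom_from_adjacency(b)[1, 2], 1)

  # identical expression profiles yield adjacency 1 to each other
  set.seed(41)
  x <- matrix(rnorm(8 * 20), 8)
  x <- rbind(x, x[1, ])                # gene 9 duplicates gene 1
  rownames(x) <- sprintf("g%02d", 1:9); colnames(x) <- sprintf("s%02d", 1:20)
  net <- build_network(x, beta = 2)
  expect_equal(net$adjacency["g01", "g09"], 1, tolerance = 1e-12)
  expect_gt(net$tom["g01", "g09"], max(net$tom["g01", -c(1, 9)]))
})

test_that("adjacency and TOM satisfy their structural invariants", {
  bf <- bundle_fixture(1)
  net <- build_network(bf$combined$expr[1:80, ], beta = 8)
  for (m in list(net$adjacency, net$tom)) {
    expect_identical(m, t(m))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
    expect_true(all(m >= 0 & m <= 1))
  }
  # raising beta strictly shrinks every off-diagonal with |r| < 1
  net2 <- build_network(bf$combined$expr[1:80, ], beta = 9)
  off <- upper.tri(net$adjacency)
  strict <- net$adjacency[off] < 1 & net$adjacency[off] > 0
  expect_true(all(net2$adjacency[off][strict] < net$adjacency[off][strict]))

  zv <- rbind(bf$combined$expr[1:10, ], flat = 0)
  expect_error(build_network(zv, beta = 6), "flat")
})

test_that("scale-free fit index is high on an exact power-law degree sequence", {
  for (seed in 1:3) {
    set.seed(seed)
    k <- (1 - runif(2000))^(-1 / 1.5)    # Pareto: p(k) ~ k^-2.5
    k <- k[k < 50]
    fit <- scale_free_fit(k)
    expect_gte(fit[["fit_r2"]], 0.8)
    expect_lt(fit[["slope"]], 0)
  }
  # anti-scale-free (uniform k) does not fool the sign convention
  set.seed(4)
  expect_lt(scale_free_fit(runif(1000, 10, 11))[["fit_r2"]], 0.8)
})

test_that("soft-threshold scan covers the range and recommends sensibly", {
  bf <- bundle_fixture(1)
  x <- bf$combined$expr[1:60, ]
  one <- scan_soft_thresholds(x, powers = 7)
  expect_equal(nrow(one), 1L)
  expect_equal(one$power, 7)

  sc <- scan_soft_thresholds(x, powers = c(1, 4, 8), fit_target = 0.8)
  expect_true(all(is.na(sc$fit_r2) | abs(sc$fit_r2) <= 1))
  expect_true(attr(sc, "recommended") %in% sc$power)
  # mean connectivity decreases with the power
  expect_true(all(diff(sc$mean_connectivity) < 0))

  # fixed replay of published power choices flows through the config untouched
  for (p in c(7, 1, 14)) {
    expect_equal(pipeline_config(power = p, power_mode = "fixed")$power, p)
  }
})

test_that("fixed-height cut recovers perfectly separated blocks and respects min size", {
  set.seed(43)
  f1 <- rnorm(30); f2 <- rnorm(30)
  x <- rbind(outer(rep(1, 15), f1), outer(rep(1, 15), f2)) +
    matrix(rnorm(30 * 30, 0, 1e-3), 30)
  dimnames(x) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:30))
  net <- build_network(x, beta = 6)
  labels <- detect_modules(net, min_module_size = 10)
  truth <- rep(1:2, each = 15)
  expect_equal(max(labels), 2)
  expect_equal(mclust::adjustedRandIndex(labels, truth), 1)

  all_grey <- detect_modules(net, min_module_size = 20)
  expect_true(all(all_grey == 0))
  expect_error(detect_modules(net, cut_height = 1.2, min_module_size = 5),
               "cut_height")
})

test_that("module recovery on the default bundle is accurate", {
  bf <- bundle_fixture(1)
  labels <- detect_modules(build_network(bf$combined, beta = 8))
  ari <- mclust::adjustedRandIndex(labels, bf$sim$truth$module_label)
  expect_gte(ari, 0.8)
})

test_that("eigengenes summarise modules optimally and kME ranks own module first", {
  set.seed(47)
  f <- rnorm(25)
  x <- outer(runif(6, 0.8, 1.2), f) + matrix(rnorm(150, 0, 1e-4), 6)
  dimnames(x) <- list(sprintf("g%d", 1:6), sprintf("s%02d", 1:25))
  labels <- setNames(rep(1L, 6), rownames(x))
  eg <- compute_eigengenes(x, labels)
  expect_equal(unname(eg$kME[, "M1"]), rep(1, 6), tolerance = 1e-4)
  expect_equal(mean(eg$ME[, "M1"]), 0, tolerance = 1e-12)
  expect_equal(sum(eg$ME[, "M1"]^2), 1, tolerance = 1e-12)

  # PCA optimality: the eigengene direction explains at least as much
  # variance as any random direction through the standardised submatrix
  z <- t(scale(t(x)))
  ve <- function(v) sum((z %*% v)^2)
  v1 <- eg$ME[, "M1"]
  for (i in 1:20) {
    v <- rnorm(25); v <- v / sqrt(sum(v^2))
    expect_gte(ve(v1) + 1e-9, ve(v))
  }

  expect_warning(compute_eigengenes(x[1, , drop = FALSE],
                                    setNames(1L, "g1")), "single gene")

  bf <- bundle_fixture(1)
  truth_labels <- bf$sim$truth$module_label
  eg2 <- compute_eigengenes(bf$combined, truth_labels)
  members <- names(truth_labels)[truth_labels > 0]
  own <- sprintf("M%d", truth_labels[members])
  own_k <- abs(eg2$kME[cbind(members, own)])
  best_other <- vapply(seq_along(members), function(i) {
    max(abs(eg2$kME[members[i], setdiff(colnames(eg2$kME), own[i])]))
  }, numeric(1))
  expect_gte(mean(own_k > best_other), 0.95)
})

test_that("eigengene-similar modules merge below the cut and not above", {
  set.seed(53)
  f <- rnorm(40)
  mk_block <- function(n, f, noise) outer(runif(n, 0.9, 1.1), f) +
    matrix(rnorm(n * length(f), 0, noise), n)
  # modules 1 and 2 share a factor (highly correlated MEs); module 3 is independent
  x <- rbind(mk_block(10, f, 0.1), mk_block(10, f, 0.1), mk_block(10, rnorm(40), 0.1))
  dimnames(x) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:40))
  labels <- setNames(rep(1:3, each = 10), rownames(x))
  res <- merge_similar_modules(x, labels, merge_cut = 0.25)
  expect_equal(length(unique(res$labels[res$labels > 0])), 2)
  expect_equal(length(unique(res$labels[1:20])), 1)

  none <- merge_similar_modules(x, labels, merge_cut = 0)
  expect_identical(none$labels, labels)

  # independent modules stay apart at the default cut
  y <- rbind(mk_block(10, rnorm(40), 0.1), mk_block(10, rnorm(40), 0.1))
  dimnames(y) <- list(sprintf("h%02d", 1:20), sprintf("s%02d", 1:40))
  lab2 <- setNames(rep(1:2, each = 10), rownames(y))
  res2 <- merge_similar_modules(y, lab2, merge_cut = 0.25)
  expect_equal(length(unique(res2$labels)), 2)
})

test_that("module-tissue correlation flags by |r| and p computed from the t formula", {
  tissues <- rep(c("PFC", "CRE"), each = 10)
  ind <- as.numeric(tissues == "PFC")
  me <- cbind(M1 = scale(ind)[, 1],
              M2 = rep(c(1, -1), 10))        # orthogonal to the indicator
  res <- module_tissue_correlation(me, tissues)
  r1 <- res[res$module == "M1" & res$tissue == "PFC", ]
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-12)
  expect_true(r1$flagged)
  r2 <- res[res$module == "M2" & res$tissue == "PFC", ]
  expect_equal(r2$r, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1)
  expect_false(r2$flagged)

  # p-value formula sanity at extreme correlation
  expect_lt(tissuemod:::cor_pvalue(0.999, 50), 1e-10)
  expect_error(module_tissue_correlation(me, rep("PFC", 20)), "constant")
})

test_that("planted tissue-elevated modules are flagged for their home tissue", {
  bf <- bundle_fixture(1)
  truth <- bf$sim$truth
  eg <- compute_eigengenes(bf$combined, truth$module_label)
  mtc <- module_tissue_correlation(eg$ME, bf$combined$samples$tissue)
  for (m in 1:4) {                     # the mean-activated programmes
    home <- truth$module_home[as.character(m)]
    row <- mtc[mtc$module == sprintf("M%d", m) & mtc$tissue == home, ]
    expect_true(row$flagged)
    others <- mtc[mtc$module == sprintf("M%d", m) & mtc$tissue != home, ]
    expect_false(any(others$flagged))
  }
})

test_that("tissue dendrogram is valid Newick with sensible topology", {
  set.seed(59)
  base <- rnorm(50)
  prof <- list(HPC = base + rnorm(50, 0, 0.1),
               STR = base + rnorm(50, 0, 0.1),
               PFC = rnorm(50), WB = rnorm(50))
  x <- do.call(cbind, lapply(prof, function(p)
    outer(p, rep(1, 5)) + matrix(rnorm(250, 0, 0.05), 50)))
  colnames(x) <- sprintf("s%02d", 1:20); rownames(x) <- sprintf("g%02d", 1:50)
  tissues <- rep(names(prof), each = 5)
  nwk <- tissue_dendrogram(x, tissues)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, names(prof))
  # HPC and STR share a profile: they must be siblings
  mrca <- ape::getMRCA(tree, c("HPC", "STR"))
  desc <- ape::extract.clade(tree, mrca)$tip.label
  expect_setequal(desc, c("HPC", "STR"))

  # identical profiles merge at height ~0
  y <- cbind(x[, 1:5], x[, 1:5])
  colnames(y) <- sprintf("s%02d", 1:10)
  nwk2 <- tissue_dendrogram(y, rep(c("A", "B"), each = 5))
  tr2 <- ape::read.tree(text = nwk2)
  expect_lt(max(tr2$edge.length), 1e-6)
})

test_that("gene screening applies strict GS and kME thresholds in flagged modules", {
  labels <- setNames(c(1L, 1L, 1L, 2L), c("a", "b", "c", "d"))
  kme <- matrix(c(0.85, 0.9, 0.95, 0.1, 0.2, 0.1, 0.05, 0.9), 4, 2,
                dimnames = list(names(labels), c("M1", "M2")))
  gs <- matrix(c(0.7, 0.6, 0.65, 0.9, 0, 0, 0, 0), 4, 2,
               dimnames = list(names(labels), c("PFC", "CRE")))
  mt <- data.frame(module = c("M1", "M2"), tissue = "PFC",
                   r = c(0.9, 0.2), p = c(1e-6, 0.5),
                   flagged = c(TRUE, FALSE))
  out <- screen_module_genes(labels, kme, gs, mt)
  expect_setequal(out$gene, c("a", "c"))   # b: GS = 0.6 exactly -> excluded
  expect_true(all(out$module == 1))
})
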