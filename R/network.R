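#' Scan soft-threshold powers for scale-free topology fit
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed,
#' connectivities `k_i = sum_j a_ij - 1` are binned into 10 equal-count bins,
#' and `log10(mean p(k))` is regressed on `log10(mean k)` per bin. The fit
#' index is `-sign(slope) * R^2`, positive when the degree distribution
#' decays (the scale-free regime), so the recommended power is the smallest
#' one reaching `fit_target`, else the argmax.
#'
#' @param X An [expression_dataset()] or gene-by-sample matrix (>= 20 genes,
#'   >= 4 samples).
#' @param powers Integer powers to scan (default 1:20).
#' @param fit_target Signed R-squared considered an adequate fit (default 0.8).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return A `SoftThresholdScan` data frame (power, fit_r2, slope,
#'   mean_connectivity) with the recommended power in attribute
#'   `"recommended"`.
#' @export
scan_soft_thresholds <- function(X, powers = 1:20, fit_target = 0.8, n_bins = 10) {
  x <- if (inherits(X, "ExpressionDataset")) X$expr else X
  if (nrow(x) < 20) stopf("need >= 20 genes for a meaningful scan")
  if (ncol(x) < 4) stopf("need >= 4 samples")
  zv <- apply(x, 1, stats::sd) == 0
  if (any(zv)) stopf("zero-variance gene(s): %s",
                     paste(rownames(x)[zv][1:min(5, sum(zv))], collapse = ", "))
  r <- abs(stats::cor(t(x)))
  diag(r) <- 0
  rows <- lapply(powers, function(beta) {
    a <- r^beta
    k <- rowSums(a)
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = beta, fit_r2 = fit["fit_r2"], slope = fit["slope"],
               mean_connectivity = mean(k))
  })
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  hit <- which(!is.na(scan$fit_r2) & scan$fit_r2 >= fit_target)
  rec <- if (length(hit)) scan$power[hit[1]] else scan$power[which.max(scan$fit_r2)]
  attr(scan, "recommended") <- rec
  attr(scan, "fit_target") <- fit_target
  class(scan) <- c("SoftThresholdScan", class(scan))
  scan
}

#' Scale-free topology fit index of a connectivity sequence
#'
#' Bins the connectivities into `n_bins` equal-width bins and regresses
#' `log10(p(k))` on `log10(mean k)` per occupied bin. Returns the fit index
#' `-sign(slope) * R^2` (positive when the degree distribution decays, the
#' scale-free regime) together with the slope.
#'
#' @param k Non-negative connectivity vector.
#' @param n_bins Number of equal-width bins (default 10).
#' @return Named numeric vector `c(fit_r2, slope)`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  brk <- seq(min(k), max(k), length.out = n_bins + 1)
  brk[1] <- brk[1] - 1e-9
  bins <- cut(k, breaks = brk, include.lowest = TRUE)
  dk <- tapply(k, bins, mean)
  pk <- as.numeric(table(bins)) / length(k)
  ok <- !is.na(dk) & dk > 0 & pk > 0
  if (sum(ok) < 3) return(c(fit_r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  slope <- unname(stats::coef(fit)[2])
  c(fit_r2 = -sign(slope) * summary(fit)$r.squared, slope = slope)
}

#' Build the weighted co-expression network
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` and the topological
#' overlap matrix
#' `T_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`,
#' computed via one matrix product. Both matrices are symmetric with unit
#' diagonal and entries in `[0, 1]`.
#'
#' @param X An [expression_dataset()] or gene-by-sample matrix.
#' @param beta Soft-threshold power (>= 1).
#' @param signed If `TRUE`, use `((1 + cor)/2)^beta` instead of `|cor|^beta`.
#' @return A `CoexpressionNetwork` list: `adjacency`, `tom`, `beta`, `genes`.
#' @export
build_network <- function(X, beta, signed = FALSE) {
  x <- if (inherits(X, "ExpressionDataset")) X$expr else X
  if (beta < 1) stopf("beta must be >= 1")
  zv <- apply(x, 1, stats::sd) == 0
  if (any(zv)) stopf("zero-variance gene(s): %s",
                     paste(rownames(x)[zv][1:min(5, sum(zv))], collapse = ", "))
  r <- stats::cor(t(x))
  if (any(!is.finite(r))) stopf("non-finite correlations in the input")
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 1
  structure(list(adjacency = a, tom = tom_from_adjacency(a), beta = beta,
                 signed = signed, genes = rownames(x)),
            class = "CoexpressionNetwork")
}

#' Topological overlap from an adjacency matrix
#'
#' @param a Symmetric adjacency with unit diagonal, entries in `[0, 1]`.
#' @return The TOM similarity matrix.
#' @export
tom_from_adjacency <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a            # removes the u = i and u = j terms (diag = 1)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  tom[!is.finite(tom)] <- 0
  tom <- (tom + t(tom)) / 2       # enforce exact symmetry against FP noise
  tom <- pmin(pmax(tom, 0), 1)    # guard the [0, 1] range against FP noise
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf("CoexpressionNetwork: %d genes, beta = %g (%s)\n",
              length(x$genes), x$beta, if (x$signed) "signed" else "unsigned"))
  invisible(x)
}

#' Detect modules by fixed-height tree cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' `D = 1 - T`, cut at `cut_height`; connected subtrees with at least
#' `min_module_size` genes become modules numbered by decreasing size, ties
#' broken by first gene index; everything else is module 0 (unassigned).
#'
#' @param net A `CoexpressionNetwork`, or a dissimilarity matrix.
#' @param cut_height Dendrogram cut height in `(0, 1]` (default 0.995).
#' @param min_module_size Minimum module size (default 30).
#' @return Named integer vector of module labels.
#' @export
detect_modules <- function(net, cut_height = 0.995, min_module_size = 30) {
  if (cut_height <= 0 || cut_height > 1) stopf("cut_height must be in (0, 1]")
  d <- if (inherits(net, "CoexpressionNetwork")) 1 - net$tom else net
  if (nrow(d) < min_module_size) {
    stopf("fewer genes (%d) than min_module_size (%d)", nrow(d), min_module_size)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  relabel_by_size(raw, min_module_size, rownames(d))
}

# renumber cluster ids by decreasing size (ties: first gene index);
# clusters below min size collapse to 0
relabel_by_size <- function(raw, min_module_size, genes = names(raw)) {
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  first_idx <- vapply(keep, function(k) which(raw == as.integer(k))[1], integer(1))
  ord <- keep[order(-as.integer(sizes[keep]), first_idx)]
  labels <- integer(length(raw))
  for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- i
  stats::setNames(labels, genes)
}

#' Module eigengenes and module membership (kME)
#'
#' The eigengene of a module is the first right-singular vector of its
#' gene-standardised submatrix: one value per sample, unit norm, zero mean,
#' sign-oriented to correlate non-negatively with the module's mean
#' expression. `kME` is the Pearson correlation of every gene with every
#' module eigengene.
#'
#' @param X An [expression_dataset()] or gene-by-sample matrix.
#' @param labels Named integer module labels (0 = unassigned, excluded).
#' @return List with `ME` (samples x modules, columns `"M<k>"`) and `kME`
#'   (genes x modules).
#' @export
compute_eigengenes <- function(X, labels) {
  x <- if (inherits(X, "ExpressionDataset")) X$expr else X
  stopifnot(identical(rownames(x), names(labels)))
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stopf("no modules to summarise")
  me <- matrix(NA_real_, nrow = ncol(x), ncol = length(mods),
               dimnames = list(colnames(x), sprintf("M%d", mods)))
  for (i in seq_along(mods)) {
    sub <- x[labels == mods[i], , drop = FALSE]
    if (nrow(sub) == 1) {
      warnf("module %d has a single gene; eigengene = its standardised profile",
            mods[i])
      v <- as.numeric(scale(sub[1, ]))
      v <- v / sqrt(sum(v^2))
    } else {
      z <- t(scale(t(sub)))            # standardise each gene across samples
      sv <- svd(z, nu = 0, nv = 1)
      v <- sv$v[, 1]
    }
    if (stats::cor(v, colMeans(sub)) < 0) v <- -v
    me[, i] <- v
  }
  kme <- stats::cor(t(x), me)
  rownames(kme) <- rownames(x)
  list(ME = me, kME = kme)
}

#' Merge modules with similar eigengenes
#'
#' Average-linkage clustering of eigengenes on `1 - cor(ME)`; branches below
#' `merge_cut` are merged, then labels are renumbered by size and eigengenes
#' and kME recomputed.
#'
#' @param X Expression (as in [compute_eigengenes()]).
#' @param labels Module labels.
#' @param merge_cut Dissimilarity threshold below which modules merge
#'   (default 0.25); 0 merges nothing.
#' @return List with `labels`, `ME`, `kME` and `merged` (logical).
#' @export
merge_similar_modules <- function(X, labels, merge_cut = 0.25) {
  x <- if (inherits(X, "ExpressionDataset")) X$expr else X
  eg <- compute_eigengenes(x, labels)
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) < 2 || merge_cut <= 0) {
    return(list(labels = labels, ME = eg$ME, kME = eg$kME, merged = FALSE))
  }
  d <- 1 - stats::cor(eg$ME)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, h = merge_cut)
  if (length(unique(grp)) == length(mods)) {
    return(list(labels = labels, ME = eg$ME, kME = eg$kME, merged = FALSE))
  }
  new_labels <- labels
  for (g in unique(grp)) {
    members <- mods[grp == g]
    new_labels[labels %in% members] <- members[1]
  }
  new_labels <- relabel_by_size(new_labels, min_module_size = 1,
                                genes = names(labels))
  new_labels[labels == 0] <- 0L
  eg2 <- compute_eigengenes(x, new_labels)
  list(labels = new_labels, ME = eg2$ME, kME = eg2$kME, merged = TRUE)
}

#' Module-tissue correlation and tissue-specific module calls
#'
#' Pearson correlation between each module eigengene and each 0/1 tissue
#' indicator, with the two-sided p-value from
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df. A module is flagged
#' tissue-specific when `|r| > r_min` and `p < p_max`.
#'
#' @param ME Samples-by-modules eigengene matrix.
#' @param tissues Character vector of per-sample tissue labels.
#' @param r_min,p_max Flagging thresholds (defaults 0.6 and 0.05, both strict).
#' @return Data frame: module, tissue, r, p, flagged.
#' @export
module_tissue_correlation <- function(ME, tissues, r_min = 0.6, p_max = 0.05) {
  stopifnot(nrow(ME) == length(tissues))
  if (nrow(ME) < 3) stopf("need >= 3 samples")
  tl <- unique(tissues)
  if (length(tl) < 2) stopf("tissue indicator is constant (single tissue)")
  n <- nrow(ME)
  out <- list()
  for (t in tl) {
    ind <- as.numeric(tissues == t)
    r <- as.numeric(stats::cor(ME, ind))
    p <- cor_pvalue(r, n)
    out[[t]] <- data.frame(module = colnames(ME), tissue = t, r = r, p = p,
                           flagged = abs(r) > r_min & p < p_max,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene significance for tissue identity
#'
#' Per-gene Pearson correlation with each 0/1 tissue indicator.
#'
#' @param X Expression (dataset or matrix).
#' @param tissues Per-sample tissue labels.
#' @return Genes-by-tissues matrix of correlations.
#' @export
gene_significance <- function(X, tissues) {
  x <- if (inherits(X, "ExpressionDataset")) X$expr else X
  stopifnot(ncol(x) == length(tissues))
  tl <- unique(tissues)
  if (length(tl) < 2) stopf("tissue indicator is constant (single tissue)")
  gs <- vapply(tl, function(t) as.numeric(stats::cor(t(x), as.numeric(tissues == t))),
               numeric(nrow(x)))
  rownames(gs) <- rownames(x)
  gs
}

#' Hierarchical clustering of tissues
#'
#' Mean expression profile per tissue, distance `1 - cor`, average linkage;
#' returned as a Newick string with branch lengths.
#'
#' @param X Expression (dataset or matrix).
#' @param tissues Per-sample tissue labels (>= 2 tissues).
#' @return Newick string.
#' @export
tissue_dendrogram <- function(X, tissues) {
  x <- if (inherits(X, "ExpressionDataset")) X$expr else X
  tl <- unique(tissues)
  if (length(tl) < 2) stopf("need >= 2 tissues")
  prof <- vapply(tl, function(t) rowMeans(x[, tissues == t, drop = FALSE]),
                 numeric(nrow(x)))
  d <- 1 - stats::cor(prof)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (length(tl) == 2) {
    # ape needs >= 3 leaves; emit the two-leaf tree directly
    h <- hc$height[1] / 2
    return(sprintf("(%s:%g,%s:%g);", tl[1], h, tl[2], h))
  }
  ape::write.tree(ape::as.phylo(hc))
}

#' Screen genes in tissue-specific modules
#'
#' For each flagged (module, tissue) pair, keeps member genes with
#' `|GS| > gs_min` and `|kME| > kme_min` (strict inequalities).
#'
#' @param labels Module labels (named by gene).
#' @param kME Genes-by-modules kME matrix (columns `"M<k>"`).
#' @param GS Genes-by-tissues gene-significance matrix.
#' @param module_tissue Data frame from [module_tissue_correlation()].
#' @param gs_min,kme_min Screening thresholds (defaults 0.6 and 0.8).
#' @return Data frame: gene, module, tissue, GS, kME, module_r, module_p.
#' @export
screen_module_genes <- function(labels, kME, GS, module_tissue,
                                gs_min = 0.6, kme_min = 0.8) {
  flagged <- module_tissue[module_tissue$flagged, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(flagged))) {
    mcol <- flagged$module[i]
    m <- as.integer(sub("^M", "", mcol))
    t <- flagged$tissue[i]
    members <- names(labels)[labels == m]
    if (!length(members)) next
    gs <- GS[members, t]
    km <- kME[members, mcol]
    keep <- abs(gs) > gs_min & abs(km) > kme_min
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <-
      data.frame(gene = members[keep], module = m, tissue = t,
                 GS = gs[keep], kME = km[keep],
                 module_r = flagged$r[i], module_p = flagged$p[i],
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene = character(), module = integer(), tissue = character(),
               GS = numeric(), kME = numeric(), module_r = numeric(),
               module_p = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
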