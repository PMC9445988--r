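#' Normalised per-dataset gene rankings
#'
#' Orders each dataset's genes by log fold change (descending for the "up"
#' list, ascending for "down"; optionally by absolute value), breaking ties
#' by gene id, and records the normalised rank `rank / N` per list. Genes
#' absent from a list carry `NA`.
#'
#' @param deg_tables Named list of `DegTable` data frames (columns `gene`,
#'   `logFC`).
#' @param direction `"up"` or `"down"`.
#' @param by Rank by `"signed"` logFC (default) or `"abs"`.
#' @return Genes-by-lists matrix of normalised ranks in `(0, 1]`.
#' @export
normalise_ranks <- function(deg_tables, direction = c("up", "down"),
                            by = c("signed", "abs")) {
  direction <- match.arg(direction)
  by <- match.arg(by)
  stopifnot(length(deg_tables) >= 1)
  if (is.null(names(deg_tables))) {
    names(deg_tables) <- sprintf("list%d", seq_along(deg_tables))
  }
  all_genes <- sort(unique(unlist(lapply(deg_tables, function(d) d$gene))))
  rmat <- matrix(NA_real_, nrow = length(all_genes), ncol = length(deg_tables),
                 dimnames = list(all_genes, names(deg_tables)))
  for (j in seq_along(deg_tables)) {
    d <- deg_tables[[j]]
    if (!all(is.finite(d$logFC))) stopf("list '%s': non-finite logFC", names(deg_tables)[j])
    dup <- d$gene[duplicated(d$gene)]
    if (length(dup)) stopf("list '%s': duplicate gene(s) %s",
                           names(deg_tables)[j], paste(unique(dup), collapse = ", "))
    key <- if (by == "abs") abs(d$logFC) else d$logFC
    if (direction == "up") key <- -key     # largest first
    ord <- order(key, d$gene)
    n <- nrow(d)
    rmat[d$gene[ord], j] <- seq_len(n) / n
  }
  rmat
}

#' Beta order-statistic scores
#'
#' For sorted normalised ranks `r_(1) <= ... <= r_(n)`, element `k` is the
#' Beta(k, n - k + 1) CDF at `r_(k)`: the probability that the k-th order
#' statistic of `n` independent uniforms is at most `r_(k)`.
#'
#' @param r_sorted Ascending numeric vector in `(0, 1]`.
#' @param n Number of lists (defaults to `length(r_sorted)`).
#' @return Vector of scores.
#' @export
beta_scores <- function(r_sorted, n = length(r_sorted)) {
  if (is.unsorted(r_sorted)) stopf("ranks must be sorted ascending")
  if (any(r_sorted <= 0 | r_sorted > 1)) stopf("ranks must lie in (0, 1]")
  k <- seq_along(r_sorted)
  stats::pbeta(r_sorted, k, n - k + 1)
}

#' Robust rank aggregation
#'
#' Per gene, `rho` is the minimum beta order-statistic score of its sorted
#' normalised ranks over the lists containing it, and
#' `p_corrected = min(1, rho * n_lists)` (Bonferroni over the minimum). A
#' gene is significant when `p_corrected < alpha` (strict).
#'
#' @param rmat Genes-by-lists matrix from [normalise_ranks()].
#' @param alpha Significance threshold (default 0.05).
#' @return An `RraResult` data frame: gene, n_lists, rho, p_corrected,
#'   significant.
#' @export
rra_aggregate <- function(rmat, alpha = 0.05) {
  in_any <- rowSums(!is.na(rmat)) > 0
  if (any(!in_any)) {
    warnf("%d gene(s) present in no list dropped", sum(!in_any))
    rmat <- rmat[in_any, , drop = FALSE]
  }
  res <- apply(rmat, 1, function(r) {
    r <- sort(r[!is.na(r)])
    n <- length(r)
    rho <- min(beta_scores(r, n))
    c(n, rho, min(1, rho * n))
  })
  out <- data.frame(gene = rownames(rmat), n_lists = as.integer(res[1, ]),
                    rho = res[2, ], p_corrected = res[3, ],
                    significant = res[3, ] < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("RraResult", class(out))
  out
}

#' Robust rank aggregation of DEG tables, both directions
#'
#' Aggregates the up- and down-regulated rankings separately and returns the
#' combined table with a `direction` column; the robust DEG set is the union
#' of significant genes from either direction.
#'
#' @inheritParams normalise_ranks
#' @param alpha Significance threshold.
#' @return Data frame: gene, direction, n_lists, rho, p_corrected, significant.
#' @export
robust_rank_aggregate <- function(deg_tables, alpha = 0.05, by = "signed") {
  out <- lapply(c("up", "down"), function(dir) {
    res <- rra_aggregate(normalise_ranks(deg_tables, direction = dir, by = by),
                         alpha = alpha)
    cbind(res[, "gene", drop = FALSE], direction = dir,
          res[, c("n_lists", "rho", "p_corrected", "significant")])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Empirical type-I calibration of the aggregation statistic
#'
#' Simulates independent uniform rankings (random permutations per list) and
#' reports the fraction of genes called significant at each `alpha`.
#'
#' @param n_lists,n_genes Grid size per replicate.
#' @param reps Number of replicates (>= 100).
#' @param seed Integer seed.
#' @param alphas Thresholds to tabulate.
#' @return Data frame: alpha, rate, n (total gene-tests).
#' @export
rra_calibrate_null <- function(n_lists, n_genes, reps = 200, seed = 1,
                               alphas = c(0.01, 0.05)) {
  if (reps < 100) stopf("reps must be >= 100 for a stable rate")
  with_seed(seed, {
    hits <- stats::setNames(numeric(length(alphas)), alphas)
    for (rep in seq_len(reps)) {
      rmat <- vapply(seq_len(n_lists),
                     function(j) sample(n_genes) / n_genes, numeric(n_genes))
      rs <- if (n_lists == 1) rmat else t(apply(rmat, 1, sort))
      k <- seq_len(n_lists)
      scores <- stats::pbeta(rs, matrix(k, n_genes, n_lists, byrow = TRUE),
                             matrix(n_lists - k + 1, n_genes, n_lists, byrow = TRUE))
      p <- pmin(1, apply(scores, 1, min) * n_lists)
      for (i in seq_along(alphas)) hits[i] <- hits[i] + sum(p < alphas[i])
    }
    data.frame(alpha = alphas, rate = as.numeric(hits) / (reps * n_genes),
               n = reps * n_genes)
  })
}
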