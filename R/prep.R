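#' Log2-normalise an expression dataset
#'
#' Applies `x -> log2(x + pseudocount)` to a linear-scale matrix. Matrices
#' that already look log-scaled (maximum value below `log_threshold`) are
#' returned unchanged with a warning, since public microarray matrices arrive
#' in both states. The transform is not idempotent: do not double-apply.
#'
#' @param ds An [expression_dataset()] (linear scale, values >= 0).
#' @param pseudocount Added before the log (default 1).
#' @param log_threshold Maximum value below which the matrix is assumed to be
#'   log-scaled already (default 30).
#' @return The dataset on log2 scale.
#' @export
log2_normalise <- function(ds, pseudocount = 1, log_threshold = 30) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (any(ds$expr < 0)) stopf("log2_normalise: negative expression values")
  if (max(ds$expr) < log_threshold) {
    warnf("matrix maximum %.3g < %g: looks log-scaled already, skipping",
          max(ds$expr), log_threshold)
    return(ds)
  }
  ds$expr <- log2(ds$expr + pseudocount)
  ds
}

#' Per-gene linear-model differential expression
#'
#' Ordinary least squares of expression on case/control status plus optional
#' covariates, per gene. The reported `logFC` is the status coefficient
#' (case minus control on the log2 scale); `t` and the two-sided `p` refer to
#' that coefficient. With no covariates this reduces exactly to the
#' equal-variance two-sample t-test.
#'
#' @param ds A log2-scale [expression_dataset()] whose metadata has a
#'   `status` column with values `"case"`/`"control"`.
#' @param covariates Character vector of metadata columns to adjust for.
#' @param deg_alpha Significance threshold for the `significant` flag
#'   (default 0.05, strict `<`).
#' @return A `DegTable` data frame: gene, logFC, t, p, significant.
#' @export
differential_expression <- function(ds, covariates = character(),
                                    deg_alpha = 0.05) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  meta <- ds$samples
  if (!all(covariates %in% names(meta))) {
    stopf("covariate column(s) missing from metadata: %s",
          paste(setdiff(covariates, names(meta)), collapse = ", "))
  }
  status <- as.integer(meta$status == "case")
  if (sum(status) < 2 || sum(1 - status) < 2) {
    stopf("need >= 2 case and >= 2 control samples")
  }
  fm <- if (length(covariates)) {
    stats::as.formula(paste("~ status +", paste(covariates, collapse = " + ")))
  } else ~status
  dd <- meta[, covariates, drop = FALSE]
  dd$status <- status
  X <- stats::model.matrix(fm, data = dd)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  H <- chol2inv(chol(crossprod(X)))
  B <- ds$expr %*% X %*% H                 # genes x coefficients
  rss <- rowSums((ds$expr - B %*% t(X))^2)
  df <- n - p
  sigma2 <- rss / df
  j <- match("status", colnames(X))
  se <- sqrt(sigma2 * H[j, j])
  tstat <- B[, j] / se
  # zero-variance genes: no evidence either way
  degenerate <- sigma2 < 1e-24 & abs(B[, j]) < 1e-12
  tstat[degenerate] <- 0
  tstat[!is.finite(tstat)] <- 0
  pval <- 2 * stats::pt(-abs(tstat), df = df)
  out <- data.frame(gene = rownames(ds$expr), logFC = B[, j], t = tstat,
                    p = pval, significant = pval < deg_alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "deg_alpha") <- deg_alpha
  class(out) <- c("DegTable", class(out))
  out
}

#' Screen genes for demographic confounder association
#'
#' Binary confounders are tested with a pooled two-sample t-test per gene;
#' continuous confounders with a Pearson correlation and its t-distributed
#' p-value (n - 2 df). A gene is excluded when any confounder associates at
#' `p < confounder_alpha`.
#'
#' @param ds A log2-scale [expression_dataset()].
#' @param confounders Character vector of metadata columns; a column with at
#'   most 2 distinct values is treated as binary, otherwise as continuous.
#' @param confounder_alpha Exclusion threshold (default 0.05).
#' @return A `ConfounderReport` list: `tests` (long data frame gene x
#'   confounder with statistic and p), `excluded` (character vector),
#'   `excluded_by` (named list).
#' @export
confounder_screen <- function(ds, confounders, confounder_alpha = 0.05) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  meta <- ds$samples
  miss <- setdiff(confounders, names(meta))
  if (length(miss)) stopf("confounder column(s) missing: %s",
                          paste(miss, collapse = ", "))
  tests <- list()
  for (cf in confounders) {
    v <- meta[[cf]]
    if (length(unique(v)) < 2) {
      warnf("confounder '%s' is constant; skipped", cf)
      next
    }
    if (is.numeric(v) && length(unique(v)) > 2) {
      # zero-variance genes yield NA correlations; treated as r = 0, p = 1
      r <- as.numeric(suppressWarnings(stats::cor(t(ds$expr), v)))
      r[!is.finite(r)] <- 0
      p <- cor_pvalue(r, length(v))
      tests[[cf]] <- data.frame(gene = rownames(ds$expr), confounder = cf,
                                statistic = r, p = p, stringsAsFactors = FALSE)
    } else {
      grp <- v == sort(unique(v))[1]
      tt <- row_ttest(ds$expr, grp)
      tests[[cf]] <- data.frame(gene = rownames(ds$expr), confounder = cf,
                                statistic = tt$t, p = tt$p,
                                stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(tests)) do.call(rbind, tests) else {
    data.frame(gene = character(), confounder = character(),
               statistic = numeric(), p = numeric(), stringsAsFactors = FALSE)
  }
  rownames(tab) <- NULL
  hits <- tab[tab$p < confounder_alpha, , drop = FALSE]
  structure(list(tests = tab,
                 excluded = unique(hits$gene),
                 excluded_by = split(hits$confounder, hits$gene),
                 confounder_alpha = confounder_alpha),
            class = "ConfounderReport")
}

#' Select differentially expressed genes
#'
#' Genes with `p < deg_alpha` (strict) that are not confounder-excluded.
#'
#' @param deg A `DegTable` from [differential_expression()].
#' @param report Optional `ConfounderReport` from [confounder_screen()].
#' @param deg_alpha Threshold; defaults to the one recorded in `deg`.
#' @return Character vector of gene ids.
#' @export
select_degs <- function(deg, report = NULL, deg_alpha = NULL) {
  if (is.null(deg_alpha)) {
    deg_alpha <- attr(deg, "deg_alpha")
    if (is.null(deg_alpha)) deg_alpha <- 0.05
  }
  sel <- deg$gene[deg$p < deg_alpha]
  if (!is.null(report)) sel <- setdiff(sel, report$excluded)
  sel
}
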