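#' Merge same-tissue datasets on their differential genes
#'
#' Concatenates the sample columns of several datasets from one tissue. The
#' gene space is the union of the per-dataset DEG sets, restricted to genes
#' measured in every member dataset, so the merged matrix has no missing
#' values. Network construction downstream uses case samples only, following
#' the study design this pipeline implements.
#'
#' @param datasets List of log2-scale [expression_dataset()] objects sharing
#'   one tissue label.
#' @param deg_sets List (same length) of character vectors of selected genes;
#'   `NULL` entries mean "all genes of that dataset".
#' @param case_only Drop control samples (default `TRUE`).
#' @return An [expression_dataset()] whose metadata `batch` column partitions
#'   the samples by source dataset.
#' @export
merge_tissue <- function(datasets, deg_sets = NULL, case_only = TRUE) {
  stopifnot(length(datasets) >= 1)
  tissues <- unique(unlist(lapply(datasets, function(d) unique(d$samples$tissue))))
  if (length(tissues) != 1) {
    stopf("datasets span multiple tissues: %s", paste(tissues, collapse = ", "))
  }
  if (is.null(deg_sets)) deg_sets <- rep(list(NULL), length(datasets))
  per_ds_genes <- lapply(seq_along(datasets), function(i) {
    g <- rownames(datasets[[i]]$expr)
    if (is.null(deg_sets[[i]])) g else intersect(deg_sets[[i]], g)
  })
  keep <- Reduce(union, per_ds_genes)
  measured_everywhere <- Reduce(intersect, lapply(datasets, function(d) rownames(d$expr)))
  keep <- intersect(keep, measured_everywhere)
  if (!length(keep)) {
    stopf("empty gene intersection; per-dataset selected gene counts: %s",
          paste(lengths(per_ds_genes), collapse = ", "))
  }
  keep <- keep[order(match(keep, rownames(datasets[[1]]$expr)))]
  parts <- lapply(datasets, function(d) {
    idx <- if (case_only) d$samples$status == "case" else rep(TRUE, ncol(d$expr))
    list(expr = d$expr[keep, idx, drop = FALSE],
         samples = d$samples[idx, , drop = FALSE])
  })
  expr <- do.call(cbind, lapply(parts, `[[`, "expr"))
  samples <- do.call(rbind, lapply(parts, `[[`, "samples"))
  rownames(samples) <- NULL
  expression_dataset(expr, samples)
}

#' Fit the empirical-Bayes location/scale batch model
#'
#' Standard parametric empirical-Bayes batch adjustment: per-gene
#' standardisation, per-batch location (`gamma`) and scale (`delta^2`)
#' estimates, shrunk toward moment-matched normal and inverse-gamma priors by
#' the closed-form iteration until the largest parameter change falls below
#' `tol`. With a single batch the model is the identity (`gamma* = 0`,
#' `delta* = 1`). Hyperprior moments that degenerate (all genes identical)
#' fall back to the unshrunk estimates.
#'
#' @param m An [expression_dataset()] whose metadata has a `batch` column.
#' @param tol Convergence tolerance on the EB iteration (default 1e-4).
#' @param max_iter Iteration cap (default 100); non-convergence warns and
#'   keeps the last iterate.
#' @return A `BatchModel` list: `batches`, `stand_mean` (per-gene alpha),
#'   `var_pooled`, `gamma_hat`/`delta_hat` (per batch x gene),
#'   `gamma_star`/`delta_star` (EB-shrunk), and the prior hyperparameters.
#' @export
fit_batch_model <- function(m, tol = 1e-4, max_iter = 100) {
  stopifnot(inherits(m, "ExpressionDataset"))
  batch <- as.character(m$samples$batch)
  batches <- unique(batch)
  nb <- table(batch)[batches]
  if (any(nb < 2) && length(batches) > 1) {
    stopf("batch(es) with a single sample (%s): pool them or drop covariates",
          paste(batches[nb < 2], collapse = ", "))
  }
  x <- m$expr
  ng <- nrow(x); n <- ncol(x)
  genes <- rownames(x)

  if (length(batches) == 1) {
    model <- list(batches = batches,
                  stand_mean = rowMeans(x),
                  var_pooled = apply(x, 1, stats::var),
                  gamma_hat = matrix(0, 1, ng, dimnames = list(batches, genes)),
                  delta_hat = matrix(1, 1, ng, dimnames = list(batches, genes)),
                  gamma_star = matrix(0, 1, ng, dimnames = list(batches, genes)),
                  delta_star = matrix(1, 1, ng, dimnames = list(batches, genes)),
                  priors = NULL, converged = TRUE, iterations = 0L)
    class(model) <- "BatchModel"
    return(model)
  }

  idx <- lapply(batches, function(b) which(batch == b))
  names(idx) <- batches
  # per-batch means, pooled (weighted) grand mean and residual variance
  bmean <- t(vapply(idx, function(i) rowMeans(x[, i, drop = FALSE]), numeric(ng)))
  w <- as.numeric(nb) / n
  stand_mean <- as.numeric(crossprod(w, bmean))
  fitted <- bmean[match(batch, batches), , drop = FALSE]
  var_pooled <- colSums((t(x) - fitted)^2) / n
  if (any(var_pooled <= 0)) {
    stopf("gene(s) with zero pooled within-batch variance: %s",
          paste(genes[var_pooled <= 0][1:min(5, sum(var_pooled <= 0))], collapse = ", "))
  }
  s <- (x - stand_mean) / sqrt(var_pooled)   # recycled by column

  gamma_hat <- t(vapply(idx, function(i) rowMeans(s[, i, drop = FALSE]), numeric(ng)))
  delta_hat <- t(vapply(idx, function(i) apply(s[, i, drop = FALSE], 1, stats::var),
                        numeric(ng)))
  dimnames(gamma_hat) <- dimnames(delta_hat) <- list(batches, genes)

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  dm <- rowMeans(delta_hat)
  s2 <- apply(delta_hat, 1, stats::var)
  a_prior <- (2 * s2 + dm^2) / s2
  b_prior <- (dm * s2 + dm^3) / s2

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  converged <- TRUE
  iters <- 0L
  for (b in seq_along(batches)) {
    nbb <- as.numeric(nb[b])
    sb <- s[, idx[[b]], drop = FALSE]
    if (!is.finite(s2[b]) || s2[b] < 1e-12 || !is.finite(t2[b]) || t2[b] < 1e-12) {
      # degenerate hyperpriors: keep method-of-moments estimates unshrunk
      gamma_star[b, ] <- gamma_hat[b, ]
      delta_star[b, ] <- delta_hat[b, ]
      next
    }
    g_old <- gamma_hat[b, ]
    d_old <- delta_hat[b, ]
    change <- Inf; it <- 0L
    while (change > tol && it < max_iter) {
      g_new <- (t2[b] * nbb * gamma_hat[b, ] + d_old * gamma_bar[b]) /
        (t2[b] * nbb + d_old)
      sum2 <- rowSums((sb - g_new)^2)  # residual SS about the shrunk mean
      d_new <- (0.5 * sum2 + b_prior[b]) / (nbb / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old + 1e-30),
                    abs(d_new - d_old) / abs(d_old + 1e-30))
      g_old <- g_new; d_old <- d_new; it <- it + 1L
    }
    if (change > tol) {
      warnf("EB iteration for batch '%s' did not converge in %d iterations (change %.2g)",
            batches[b], max_iter, change)
      converged <- FALSE
    }
    iters <- max(iters, it)
    gamma_star[b, ] <- g_old
    delta_star[b, ] <- d_old
  }

  model <- list(batches = batches, stand_mean = stats::setNames(stand_mean, genes),
                var_pooled = stats::setNames(var_pooled, genes),
                gamma_hat = gamma_hat, delta_hat = delta_hat,
                gamma_star = gamma_star, delta_star = delta_star,
                priors = list(gamma_bar = gamma_bar, t2 = t2,
                              a_prior = a_prior, b_prior = b_prior),
                converged = converged, iterations = iters)
  class(model) <- "BatchModel"
  model
}

#' Apply a fitted batch model
#'
#' `x* = (x - alpha - gamma*) * sd_pooled / delta* + alpha` per gene and
#' batch, leaving the matrix shape untouched.
#'
#' @param m An [expression_dataset()] with the same design the model was
#'   fitted on.
#' @param model A `BatchModel` from [fit_batch_model()].
#' @return The adjusted dataset.
#' @export
apply_batch_model <- function(m, model) {
  stopifnot(inherits(m, "ExpressionDataset"), inherits(model, "BatchModel"))
  batch <- as.character(m$samples$batch)
  unknown <- setdiff(unique(batch), model$batches)
  if (length(unknown)) stopf("batch label(s) absent from model: %s",
                             paste(unknown, collapse = ", "))
  if (length(model$batches) == 1) return(m)
  x <- m$expr
  sdp <- sqrt(model$var_pooled)
  s <- (x - model$stand_mean) / sdp
  for (b in model$batches) {
    i <- which(batch == b)
    s[, i] <- (s[, i] - model$gamma_star[b, ]) / sqrt(model$delta_star[b, ])
  }
  m$expr <- s * sdp + model$stand_mean
  m
}

#' Fit and apply the batch model in one step
#'
#' @inheritParams fit_batch_model
#' @return The adjusted dataset with the fitted model attached as attribute
#'   `"batch_model"`.
#' @export
remove_batch_effects <- function(m, tol = 1e-4, max_iter = 100) {
  model <- fit_batch_model(m, tol = tol, max_iter = max_iter)
  out <- apply_batch_model(m, model)
  attr(out, "batch_model") <- model
  out
}

#' Before/after batch-adjustment diagnostics
#'
#' Per-sample median and IQR plus two summary rows of the per-gene one-way
#' batch F statistics (median and mean), before vs after adjustment. The
#' result has `n_samples + 2` rows.
#'
#' @param before,after Matched [expression_dataset()] objects.
#' @return Data frame: row_type, id, median_before, iqr_before,
#'   median_after, iqr_after.
#' @export
batch_diagnostics <- function(before, after) {
  stopifnot(identical(dim(before$expr), dim(after$expr)))
  med_b <- apply(before$expr, 2, stats::median)
  med_a <- apply(after$expr, 2, stats::median)
  iqr_b <- apply(before$expr, 2, stats::IQR)
  iqr_a <- apply(after$expr, 2, stats::IQR)
  per_sample <- data.frame(row_type = "sample", id = colnames(before$expr),
                           median_before = med_b, iqr_before = iqr_b,
                           median_after = med_a, iqr_after = iqr_a,
                           stringsAsFactors = FALSE)
  f_b <- row_anova_f(before$expr, before$samples$batch)
  f_a <- row_anova_f(after$expr, after$samples$batch)
  fsum <- data.frame(row_type = "batch_F",
                     id = c("median", "mean"),
                     median_before = c(stats::median(f_b, na.rm = TRUE),
                                       mean(f_b, na.rm = TRUE)),
                     iqr_before = NA_real_,
                     median_after = c(stats::median(f_a, na.rm = TRUE),
                                      mean(f_a, na.rm = TRUE)),
                     iqr_after = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(per_sample, fsum)
  rownames(out) <- NULL
  out
}

#' Combine per-tissue matrices into the cross-tissue network matrix
#'
#' Column-binds the (batch-adjusted, case-only) tissue matrices. The gene
#' space is the union of the per-tissue gene sets restricted to genes present
#' in every contributing tissue matrix; a tissue missing such genes entirely
#' is an error rather than an imputation target.
#'
#' @param tissue_matrices Named list of [expression_dataset()] objects, one
#'   per tissue.
#' @return An [expression_dataset()] covering all tissues.
#' @export
combine_tissues <- function(tissue_matrices) {
  stopifnot(length(tissue_matrices) >= 1)
  shared <- Reduce(intersect, lapply(tissue_matrices, function(d) rownames(d$expr)))
  if (!length(shared)) stopf("no gene present in every tissue matrix")
  shared <- shared[order(match(shared, rownames(tissue_matrices[[1]]$expr)))]
  expr <- do.call(cbind, lapply(tissue_matrices, function(d) {
    d$expr[shared, , drop = FALSE]
  }))
  samples <- do.call(rbind, lapply(tissue_matrices, function(d) d$samples))
  rownames(samples) <- NULL
  expression_dataset(expr, samples)
}
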