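#' Quantile-scale one TOM onto another
#'
#' Raises the target TOM elementwise to the power
#' `log(quantile_q(ref)) / log(quantile_q(target))`, where the quantiles are
#' taken over the strict upper-triangle entries (linear-interpolation
#' definition). After scaling the two off-diagonal `q`-quantiles agree, so
#' the two networks' topological-overlap distributions are comparable before
#' taking a consensus. The transform is monotone, keeps entries in `[0, 1]`
#' and leaves the diagonal at 1.
#'
#' @param reference,target TOM matrices over the same gene set.
#' @param q Quantile to match (default 0.98).
#' @return A `ScaledTomPair` list: `reference`, `target` (scaled),
#'   `exponent`, `q`, and the pre-scaling quantiles.
#' @export
scale_tom <- function(reference, target, q = 0.98) {
  check_tom_pair(reference, target)
  qr_ <- offdiag_quantile(reference, q)
  qt_ <- offdiag_quantile(target, q)
  if (qr_ <= 0 || qr_ >= 1 || qt_ <= 0 || qt_ >= 1) {
    stopf("off-diagonal %g-quantiles must lie in (0, 1); got ref %.4g, target %.4g",
          q, qr_, qt_)
  }
  expo <- log(qr_) / log(qt_)
  # the closed form matches order statistics exactly, but the interpolated
  # quantile of the powered matrix can drift by ~1e-8; polish numerically so
  # the post-scaling quantiles agree to full precision
  gap <- function(e) offdiag_quantile(target^e, q) - qr_
  if (abs(gap(expo)) > 1e-12) {
    expo <- stats::uniroot(gap, interval = c(expo / 2, expo * 2),
                           tol = 1e-14)$root
  }
  scaled <- target^expo
  diag(scaled) <- 1
  structure(list(reference = reference, target = scaled, exponent = expo,
                 q = q, quantile_reference = qr_, quantile_target = qt_),
            class = "ScaledTomPair")
}

offdiag_quantile <- function(m, q) {
  stats::quantile(m[upper.tri(m)], probs = q, names = FALSE, type = 7)
}

check_tom_pair <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!identical(dim(a), dim(b))) stopf("TOM dimensions differ")
  ga <- rownames(a); gb <- rownames(b)
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb)) {
    d <- union(setdiff(ga, gb), setdiff(gb, ga))
    stopf("TOM gene sets differ%s",
          if (length(d)) paste0(": ", paste(d[1:min(5, length(d))], collapse = ", "))
          else " (same genes, different order)")
  }
  invisible(TRUE)
}

#' Consensus topological overlap
#'
#' Elementwise minimum of two (quantile-scaled) TOMs: only gene pairs with
#' strong overlap in both conditions keep strong consensus overlap.
#'
#' @param scaled A `ScaledTomPair` from [scale_tom()], or a TOM matrix (then
#'   `target` must be supplied).
#' @param target Second TOM when `scaled` is a plain matrix.
#' @return The consensus TOM matrix.
#' @export
consensus_tom <- function(scaled, target = NULL) {
  if (inherits(scaled, "ScaledTomPair")) {
    a <- scaled$reference; b <- scaled$target
  } else {
    a <- scaled; b <- target
    check_tom_pair(a, b)
  }
  cons <- pmin(a, b)
  dimnames(cons) <- dimnames(a)
  cons
}

#' Merge two module-tissue correlation tables under sign consistency
#'
#' A (module, tissue) cell is consistent when the two correlations share a
#' strict sign (`r_A * r_B > 0`); the combined correlation is the
#' smaller-magnitude one (sign preserved) and the combined p the larger of
#' the two, the conservative completion. Inconsistent cells carry `NA`.
#' Consensus tissue-specific flags apply `|combined_r| > r_min` and
#' `combined_p < p_max` on consistent cells only.
#'
#' @param table_a,table_b Data frames from [module_tissue_correlation()] over
#'   the same (module, tissue) index.
#' @param r_min,p_max Flagging thresholds (defaults 0.6, 0.05).
#' @return A `ConsensusCorTable` data frame: module, tissue, r_a, p_a, r_b,
#'   p_b, consistent, combined_r, combined_p, flagged.
#' @export
merge_correlation_tables <- function(table_a, table_b, r_min = 0.6, p_max = 0.05) {
  key_a <- paste(table_a$module, table_a$tissue)
  key_b <- paste(table_b$module, table_b$tissue)
  if (!setequal(key_a, key_b) || anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stopf("module x tissue indices differ between the two tables")
  }
  table_b <- table_b[match(key_a, key_b), , drop = FALSE]
  consistent <- table_a$r * table_b$r > 0
  combined_r <- ifelse(consistent,
                       sign(table_a$r) * pmin(abs(table_a$r), abs(table_b$r)),
                       NA_real_)
  combined_p <- ifelse(consistent, pmax(table_a$p, table_b$p), NA_real_)
  out <- data.frame(module = table_a$module, tissue = table_a$tissue,
                    r_a = table_a$r, p_a = table_a$p,
                    r_b = table_b$r, p_b = table_b$p,
                    consistent = consistent,
                    combined_r = combined_r, combined_p = combined_p,
                    flagged = !is.na(combined_r) & abs(combined_r) > r_min &
                      combined_p < p_max,
                    stringsAsFactors = FALSE)
  class(out) <- c("ConsensusCorTable", class(out))
  out
}
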