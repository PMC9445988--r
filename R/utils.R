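# internal helpers shared across the pipeline

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded simulation calls do
#' not perturb surrounding code.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stage seed from a root seed; kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 101L + as.integer(offset)) %% 2147483587L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# two-sided p-value for a Pearson correlation on n observations
cor_pvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2))
  p[!is.finite(p)] <- 1
  p
}

# pooled-variance two-sample t test across matrix rows (genes x samples)
row_ttest <- function(x, grp) {
  stopifnot(is.logical(grp), length(grp) == ncol(x))
  n1 <- sum(grp); n2 <- sum(!grp)
  if (n1 < 2 || n2 < 2) stopf("each group needs >= 2 samples (got %d/%d)", n1, n2)
  m1 <- rowMeans(x[, grp, drop = FALSE])
  m2 <- rowMeans(x[, !grp, drop = FALSE])
  v1 <- apply(x[, grp, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, !grp, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[!is.finite(t)] <- 0
  p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
  list(diff = m1 - m2, t = t, p = p)
}

# one-way ANOVA F statistic per row for a grouping factor
row_anova_f <- function(x, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(x)
  if (k < 2) return(rep(NA_real_, nrow(x)))
  gm <- rowMeans(x)
  ssb <- rep(0, nrow(x))
  ssw <- rep(0, nrow(x))
  for (lev in levels(groups)) {
    idx <- groups == lev
    mg <- rowMeans(x[, idx, drop = FALSE])
    ssb <- ssb + sum(idx) * (mg - gm)^2
    ssw <- ssw + rowSums((x[, idx, drop = FALSE] - mg)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[!is.finite(f)] <- NA_real_
  f
}
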