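#' Construct an expression dataset
#'
#' Bundles a gene-by-sample expression matrix with per-sample metadata, the
#' basic container every pipeline stage consumes. Metadata rows are matched to
#' matrix columns by `sample_id`.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @param samples Data frame with at least a `sample_id` column; the pipeline
#'   additionally expects `tissue`, `status` (`"case"`/`"control"`) and
#'   `batch` columns, plus any demographic covariates (`age`, `sex`, `ph`).
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `expr` and `samples`.
#' @export
expression_dataset <- function(expr, samples) {
  if (!is.matrix(expr) || !is.numeric(expr)) stopf("`expr` must be a numeric matrix")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr))) {
    stopf("`expr` needs unique rownames (gene ids)")
  }
  if (is.null(colnames(expr))) stopf("`expr` needs colnames (sample ids)")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples)) stopf("`samples` needs a sample_id column")
  if (!identical(colnames(expr), as.character(samples$sample_id))) {
    stopf("colnames(expr) must equal samples$sample_id in order")
  }
  structure(list(expr = expr, samples = samples), class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples\n",
              nrow(x$expr), ncol(x$expr)))
  if ("tissue" %in% names(x$samples)) {
    cat("  tissues:", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  }
  if ("status" %in% names(x$samples)) {
    cat("  status: ", paste(sprintf("%s=%d", names(table(x$samples$status)),
                                    as.integer(table(x$samples$status))),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write an expression matrix as TSV
#'
#' The on-disk format is tab-separated with a header row; the first column
#' holds gene ids, remaining columns are samples. Values are written with 17
#' significant digits so a write/read round trip is bit-stable for doubles.
#'
#' @param path File path.
#' @return `read_expression_tsv()`: a numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("%s: expected a gene column plus >=1 sample column", path)
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stopf("%s: duplicate gene id(s): %s", path,
                         paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stopf("%s: non-numeric cells in column '%s'", path, names(df[-1])[bad])
  }
  rownames(m) <- genes
  m
}

#' @param m Numeric matrix with gene rownames and sample colnames.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, open = "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                        collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write the per-sample metadata table
#'
#' @param path File path.
#' @return A data frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stopf("%s: missing sample_id column", path)
  df
}

#' @param samples Data frame of sample metadata.
#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression dataset (matrix + metadata pair)
#'
#' @param expr_path,meta_path Paths to the expression TSV and metadata TSV.
#' @return An `ExpressionDataset`.
#' @export
read_expression_dataset <- function(expr_path, meta_path) {
  m <- read_expression_tsv(expr_path)
  s <- read_sample_metadata(meta_path)
  s <- s[match(colnames(m), s$sample_id), , drop = FALSE]
  rownames(s) <- NULL
  expression_dataset(m, s)
}
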