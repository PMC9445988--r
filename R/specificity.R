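#' Call tissue-specific genes
#'
#' The headline join: genes screened from tissue-specific modules
#' (`|GS| > gs_min`, `|kME| > kme_min`) that also carry independent evidence
#' from robust rank aggregation or GWAS proximity, minus confounder-excluded
#' genes. Evidence is a union by default (`"or"`); `"and"` requires both.
#'
#' @param screened Data frame from [screen_module_genes()].
#' @param rra_genes Character vector of RRA-significant genes.
#' @param gwas_genes Character vector of GWAS-window genes.
#' @param confounder_excluded Character vector of genes to drop.
#' @param mode `"or"` (default) or `"and"`.
#' @return The screened table restricted to called genes, with an `evidence`
#'   column in `{"RRA", "GWAS", "both"}`.
#' @export
call_tissue_specific_genes <- function(screened, rra_genes = character(),
                                       gwas_genes = character(),
                                       confounder_excluded = character(),
                                       mode = c("or", "and")) {
  mode <- match.arg(mode)
  in_rra <- screened$gene %in% rra_genes
  in_gwas <- screened$gene %in% gwas_genes
  keep <- if (mode == "or") in_rra | in_gwas else in_rra & in_gwas
  keep <- keep & !(screened$gene %in% confounder_excluded)
  out <- screened[keep, , drop = FALSE]
  out$evidence <- ifelse(in_rra[keep] & in_gwas[keep], "both",
                         ifelse(in_rra[keep], "RRA", "GWAS"))
  rownames(out) <- NULL
  out
}

#' Tissue-specific genes shared between two disease analyses
#'
#' Rows whose (gene, tissue) pair is called in both analyses.
#'
#' @param calls_a,calls_b Tables from [call_tissue_specific_genes()].
#' @return The rows of `calls_a` shared with `calls_b`, with `context = "shared"`.
#' @export
shared_tissue_genes <- function(calls_a, calls_b) {
  key_a <- paste(calls_a$gene, calls_a$tissue)
  key_b <- paste(calls_b$gene, calls_b$tissue)
  out <- calls_a[key_a %in% key_b, , drop = FALSE]
  if (nrow(out)) out$context <- "shared" else out$context <- character(0)
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a gene list against each gene set
#' (intersected with the universe first), with Benjamini-Hochberg adjustment
#' across sets. Equivalent to the one-sided Fisher exact test on the 2x2
#' overlap table.
#'
#' @param gene_list Character vector (will be intersected with `universe`;
#'   genes outside it warn).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of the background gene space; defaults
#'   here should be the genes entering the network, not the genome.
#' @return An `OraResult` data frame: set, overlap, set_size, list_size,
#'   universe_size, p, q.
#' @export
over_representation <- function(gene_list, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warnf("%d list gene(s) outside the universe dropped", length(outside))
  }
  gene_list <- unique(intersect(gene_list, universe))
  N <- length(universe); L <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    set <- unique(intersect(sets[[nm]], universe))
    K <- length(set)
    k <- length(intersect(gene_list, set))
    p <- if (K == 0 || L == 0) 1 else
      stats::phyper(k - 1, K, N - K, L, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, list_size = L,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("OraResult", class(out))
  out
}

#' Read / write GMT gene-set collections
#'
#' GMT: one set per line, tab-separated `name`, `description`, then member
#' genes.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stopf("malformed GMT line: %s", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' @param sets Named list of character vectors.
#' @param description Per-set description column (recycled).
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
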