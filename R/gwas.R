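#' Merge recurring variants
#'
#' Keeps one record per rsID (the first; conflicting positions warn).
#' Records sharing a position under different rsIDs are kept.
#'
#' @param variants Data frame with columns `rsid`, `chrom`, `pos` (1-based),
#'   `trait`.
#' @return Deduplicated variant table.
#' @export
dedupe_variants <- function(variants) {
  check_variant_table(variants)
  if (!nrow(variants)) return(variants)
  conflicts <- 0L
  for (id in unique(variants$rsid[duplicated(variants$rsid)])) {
    rows <- variants[variants$rsid == id, ]
    if (nrow(unique(rows[, c("chrom", "pos")])) > 1) conflicts <- conflicts + 1L
  }
  if (conflicts > 0) {
    warnf("%d rsID(s) with conflicting positions; first occurrence kept", conflicts)
  }
  out <- variants[!duplicated(variants$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_variant_table <- function(variants) {
  need <- c("rsid", "chrom", "pos", "trait")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stopf("variant table missing column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- which(!is.finite(variants$pos) | variants$pos < 1 |
                 variants$pos != floor(variants$pos))
  if (length(bad)) stopf("malformed position at row(s) %s",
                         paste(bad[1:min(5, length(bad))], collapse = ", "))
  invisible(TRUE)
}

#' Map variants to genes by window overlap
#'
#' A gene is hit when its interval lies within `window` bp of the variant
#' locus: the 1-based closed window `[pos - window, pos + window]` overlaps
#' the gene's interval (BED input, 0-based half-open). Distance is 0 for
#' intragenic variants, otherwise bp from the locus to the nearest interval
#' edge; hits satisfy `distance <= window`. Strand is ignored.
#'
#' @param variants Deduplicated variant table (see [dedupe_variants()]).
#' @param genes Data frame in BED convention: `chrom`, `start`, `end`,
#'   `gene` (0-based half-open intervals).
#' @param window Half-width in bp (default 20000).
#' @return List with `genes` (character vector, the mapped gene set) and
#'   `hits` (data frame: gene, rsid, distance).
#' @export
map_variants_to_genes <- function(variants, genes, window = 20000) {
  check_variant_table(variants)
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(genes)))
  hits <- list()
  for (chr in unique(variants$chrom)) {
    v <- variants[variants$chrom == chr, , drop = FALSE]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (!nrow(g)) {
      warnf("chromosome '%s' absent from gene annotation; %d variant(s) skipped",
            chr, nrow(v))
      next
    }
    # 1-based closed coordinates for both
    gene_rng <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    win_rng <- IRanges::IRanges(start = pmax(1L, v$pos - window),
                                end = v$pos + window)
    ov <- IRanges::findOverlaps(win_rng, gene_rng)
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    pos <- v$pos[qi]
    gstart <- g$start[si] + 1L; gend <- g$end[si]
    dist <- pmax(0L, pmax(gstart - pos, pos - gend))
    hits[[chr]] <- data.frame(gene = g$gene[si], rsid = v$rsid[qi],
                              distance = as.integer(dist),
                              stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else {
    data.frame(gene = character(), rsid = character(), distance = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  list(genes = unique(hits$gene), hits = hits)
}

#' Load a GWAS catalog extract
#'
#' Reads a TSV with columns `rsid`, `chrom`, `pos`, `trait` (1-based
#' positions), optionally filtering to a set of trait strings.
#'
#' @param path TSV path.
#' @param traits Optional character vector of traits to keep.
#' @return A validated variant table.
#' @export
load_gwas_catalog_extract <- function(path, traits = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "trait")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  if (nrow(df)) {
    suppressWarnings(posn <- as.numeric(df$pos))
    bad <- which(!is.finite(posn))
    if (length(bad)) stopf("%s: malformed position at line %d", path, bad[1] + 1L)
    df$pos <- posn
  }
  if (!is.null(traits)) df <- df[df$trait %in% traits, , drop = FALSE]
  rownames(df) <- NULL
  check_variant_table(df)
  df
}

#' Read a BED file of gene intervals
#'
#' @param path BED path (chrom, start, end, name; 0-based half-open, no
#'   header).
#' @return Data frame: chrom, start, end, gene.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stopf("%s: expected >= 4 BED columns", path)
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "gene")
  df
}
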