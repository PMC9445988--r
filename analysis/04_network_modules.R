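#!/usr/bin/env Rscript
# Cross-tissue weighted co-expression networks per cohort: soft-threshold
# scan (power 8 fixed for the network itself), TOM, fixed-height module
# detection, eigengene merging, kME/GS, and module-tissue correlation with
# the |r| > 0.6 & p < 0.05 tissue-specific flags and the
# |GS| > 0.6 & |kME| > 0.8 gene screen.

suppressPackageStartupMessages(library(tissuemod))

power <- 8
for (disease in c("a", "b")) {
  merged_dir <- file.path("results/merged", disease)
  out_dir <- file.path("results/network", disease)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tissues <- sub("^expr_(.*)\\.tsv$", "\\1",
                 list.files(merged_dir, pattern = "^expr_"))
  mats <- lapply(tissues, function(t) {
    read_expression_dataset(file.path(merged_dir, sprintf("expr_%s.tsv", t)),
                            file.path(merged_dir, sprintf("meta_%s.tsv", t)))
  })
  combined <- combine_tissues(mats)

  scan <- scan_soft_thresholds(combined, powers = c(1, 2, 4, 6, 8, 10, 12))
  write.table(scan, file.path(out_dir, "soft_threshold_scan.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  net <- build_network(combined, beta = power)
  labels <- detect_modules(net)
  mm <- merge_similar_modules(combined, labels)
  tis <- combined$samples$tissue
  mtc <- module_tissue_correlation(mm$ME, tis)
  gs <- gene_significance(combined, tis)
  screened <- screen_module_genes(mm$labels, mm$kME, gs, mtc)

  write_expression_tsv(combined$expr, file.path(out_dir, "combined_expr.tsv"))
  write_sample_metadata(combined$samples, file.path(out_dir, "combined_meta.tsv"))
  write.table(data.frame(gene = names(mm$labels), module = mm$labels),
              file.path(out_dir, "modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mtc, file.path(out_dir, "module_tissue_cor.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(screened, file.path(out_dir, "screened_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(tissue_dendrogram(combined, tis), file.path(out_dir, "tissues.nwk"))

  flagged <- mtc[mtc$flagged, ]
  message(sprintf(
    "cohort %s: %d genes, %d modules, %d tissue-specific module calls (%s); %d screened genes",
    toupper(disease), nrow(combined$expr), max(mm$labels), nrow(flagged),
    paste(sprintf("%s~%s r=%.2f", flagged$module, flagged$tissue, flagged$r),
          collapse = ", "),
    nrow(screened)))
}
message("done: network outputs under results/network/")
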