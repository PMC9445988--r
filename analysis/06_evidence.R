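#!/usr/bin/env Rscript
# Independent evidence streams: robust rank aggregation of the per-dataset
# DEG rankings within each tissue, and +/-20 kb window mapping of the toy
# GWAS variants (recurring variants merged first).

suppressPackageStartupMessages(library(tissuemod))

for (disease in c("a", "b")) {
  deg_dir <- file.path("results/deg", disease)
  data_dir <- file.path("results/data", disease)
  out_dir <- file.path("results/evidence", disease)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  deg_files <- list.files(deg_dir, pattern = "^deg_", full.names = TRUE)
  names(deg_files) <- sub("^deg_(.*)\\.tsv$", "\\1", basename(deg_files))
  tabs <- lapply(deg_files, read.table, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)
  tissue_of <- sub("_[0-9]+$", "", names(tabs))

  rra_all <- list()
  for (t in unique(tissue_of)) {
    res <- robust_rank_aggregate(tabs[tissue_of == t])
    res$tissue <- t
    rra_all[[t]] <- res
  }
  rra_all <- do.call(rbind, rra_all)
  write.table(rra_all, file.path(out_dir, "rra.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_sig <- tapply(rra_all$significant, rra_all$tissue, sum)
  message(sprintf("cohort %s: robust DEGs per tissue: %s", toupper(disease),
                  paste(sprintf("%s=%d", names(n_sig), n_sig), collapse = "  ")))

  variants <- load_gwas_catalog_extract(file.path(data_dir, "variants.tsv"))
  genes_bed <- read_bed(file.path(data_dir, "genes.bed"))
  mapped <- map_variants_to_genes(dedupe_variants(variants), genes_bed,
                                  window = 20000)
  write.table(mapped$hits, file.path(out_dir, "gwas_hits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("cohort %s: %d variants (%d after merge) -> %d window genes",
                  toupper(disease), nrow(variants),
                  nrow(dedupe_variants(variants)), length(mapped$genes)))
}
message("done: evidence tables under results/evidence/")
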