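#!/usr/bin/env Rscript
# Per-dataset differential expression (case vs control, p < 0.05) and
# demographic confounder screening, from the fixture bundles on disk.

suppressPackageStartupMessages(library(tissuemod))

for (disease in c("a", "b")) {
  data_dir <- file.path("results/data", disease)
  out_dir <- file.path("results/deg", disease)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  expr_files <- list.files(data_dir, pattern = "^expr_", full.names = TRUE)
  n_deg <- integer()
  for (f in expr_files) {
    nm <- sub("^expr_(.*)\\.tsv$", "\\1", basename(f))
    ds <- read_expression_dataset(f, file.path(data_dir, sprintf("meta_%s.tsv", nm)))
    ds <- log2_normalise(ds)
    deg <- differential_expression(ds)
    scr <- confounder_screen(ds, c("age", "sex", "ph"))
    deg$excluded_by <- vapply(deg$gene, function(g) {
      paste(scr$excluded_by[[g]], collapse = ";")
    }, character(1))
    write.table(deg, file.path(out_dir, sprintf("deg_%s.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    n_deg[nm] <- length(select_degs(deg, scr))
  }
  message(sprintf("cohort %s: DEG counts per dataset (p < 0.05, confounders removed):",
                  toupper(disease)))
  message("  ", paste(sprintf("%s=%d", names(n_deg), n_deg), collapse = "  "))
}
message("done: per-dataset DEG tables under results/deg/")
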