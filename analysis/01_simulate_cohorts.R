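#!/usr/bin/env Rscript
# Simulate the two synthetic disease cohorts (A: all five planted modules;
# B: the covariance-only PFC module absent) plus toy GWAS fixtures, and write
# the fixture bundles under results/data/.

suppressPackageStartupMessages(library(tissuemod))

seed <- 1
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg_a <- sim_config(seed = seed * 101 + 1)
pm <- default_planted_modules()
cfg_b <- sim_config(planted_modules = pm[pm$module != 5, ], seed = seed * 101 + 2)

for (disease in c("a", "b")) {
  cfg <- if (disease == "a") cfg_a else cfg_b
  sim <- simulate_study(cfg)
  gwas <- simulate_gwas_fixture(sim$truth, window_hits = 10, decoys = 10,
                                seed = seed * 101 + 10 + match(disease, c("a", "b")))
  out <- file.path("results/data", disease)
  man <- write_fixture_bundle(sim$datasets, sim$truth, out, gwas = gwas)
  message(sprintf("cohort %s: %d datasets, %d genes, %d planted modules -> %s",
                  toupper(disease), length(sim$datasets), length(sim$truth$genes),
                  length(sim$truth$module_home), out))
}
message("done: seeded fixture bundles written with manifests")
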