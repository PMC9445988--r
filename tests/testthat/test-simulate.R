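test_that("identical seeds give identical studies, different seeds differ", {
  s1 <- simulate_study(sim_config(seed = 1))
  s2 <- simulate_study(sim_config(seed = 1))
  s3 <- simulate_study(sim_config(seed = 2))
  expect_identical(s1$datasets[[1]]$expr, s2$datasets[[1]]$expr)
  expect_identical(s1$truth$de_genes, s2$truth$de_genes)
  expect_false(identical(s1$datasets[[1]]$expr, s3$datasets[[1]]$expr))
})

test_that("planted module correlates in its home tissue only (noise-free limit)", {
  pm <- data.frame(module = 1, size = 10, home_tissue = "PFC",
                   factor_mean = 0, factor_sd = 1,
                   loading_min = 1, loading_max = 1)
  cfg <- sim_config(tissues = c("PFC", "CRE"), datasets_per_tissue = 1,
                    samples_per_dataset = 40, n_genes = 100,
                    planted_modules = pm, n_de_genes = 1, de_effect = 0,
                    de_cover_modules = FALSE,
                    batch_shift_sd = 1e-9, batch_scale_sd = 1e-9,
                    confounders = data.frame(name = character(), type = character(),
                                             n_affected_genes = integer(),
                                             effect = numeric()),
                    noise_sd = 1e-6, seed = 7)
  s <- simulate_study(cfg)
  members <- names(s$truth$module_label)[s$truth$module_label == 1]
  home <- log2(s$datasets$PFC_1$expr[members, ])
  r_home <- cor(t(home))
  expect_true(all(r_home[upper.tri(r_home)] > 0.999))

  # away from home the factor is inactive: module genes look like background
  away <- log2(s$datasets$CRE_1$expr)
  r_away <- abs(cor(t(away)))
  mod_idx <- which(rownames(away) %in% members)
  within <- r_away[mod_idx, mod_idx][upper.tri(diag(length(mod_idx)))]
  bg <- r_away[-mod_idx, -mod_idx][upper.tri(diag(nrow(away) - length(mod_idx)))]
  expect_gt(t.test(within, bg)$p.value, 0.01)
})

test_that("within-module correlation margin grows with loading", {
  margins <- vapply(c(0.4, 0.8, 1.2), function(lo) {
    pm <- data.frame(module = 1, size = 20, home_tissue = "PFC",
                     factor_mean = 0, factor_sd = 2,
                     loading_min = lo, loading_max = lo)
    cfg <- sim_config(tissues = "PFC", datasets_per_tissue = 1,
                      samples_per_dataset = 60, n_genes = 200,
                      planted_modules = pm, n_de_genes = 1, de_effect = 0,
                      de_cover_modules = FALSE,
                      batch_shift_sd = 1e-9, batch_scale_sd = 1e-9,
                      confounders = default_confounders()[0, ],
                      noise_sd = 1, seed = 11)
    s <- simulate_study(cfg)
    x <- log2(s$datasets$PFC_1$expr)
    r <- abs(cor(t(x)))
    mod <- which(s$truth$module_label == 1)
    mean(r[mod, mod][upper.tri(diag(length(mod)))]) -
      mean(r[-mod, -mod][upper.tri(diag(nrow(x) - length(mod)))])
  }, numeric(1))
  expect_true(all(diff(margins) > 0))
})

test_that("planted DE genes have stochastically smaller t-test p-values", {
  cfg <- sim_config(tissues = "PFC", datasets_per_tissue = 1,
                    samples_per_dataset = 40, n_genes = 600,
                    planted_modules = default_planted_modules()[0, ],
                    n_de_genes = 100, de_cover_modules = FALSE, seed = 13)
  s <- simulate_study(cfg)
  deg <- differential_expression(log2_normalise(s$datasets$PFC_1))
  p_de <- deg$p[deg$gene %in% s$truth$de_genes]
  p_null <- deg$p[!deg$gene %in% s$truth$de_genes]
  ks <- suppressWarnings(ks.test(p_de, p_null, alternative = "greater"))
  expect_lt(ks$p.value, 0.01)
})

test_that("invalid configurations are rejected", {
  pm <- default_planted_modules()
  pm$size <- 200  # 5 x 200 > 450
  expect_error(sim_config(planted_modules = pm), "sum")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(datasets_per_tissue = 0), "count")
  pm2 <- default_planted_modules()
  pm2$home_tissue[1] <- "KIDNEY"
  expect_error(sim_config(planted_modules = pm2), "unknown home tissue")
})

test_that("gwas fixture geometry places hits inside and decoys outside windows", {
  s <- simulate_study(sim_config(seed = 3))
  gw <- simulate_gwas_fixture(s$truth, window_hits = 5, decoys = 3, seed = 5)
  dd <- dedupe_variants(gw$variants)
  expect_equal(nrow(gw$variants) - nrow(dd), 1)  # one recurring rsID planted
  mapped <- map_variants_to_genes(dd, gw$genes, window = 20000)
  expect_setequal(mapped$genes, gw$hit_genes)
  expect_true(all(mapped$hits$distance <= 20000))

  empty <- simulate_gwas_fixture(s$truth, window_hits = 0, decoys = 0, seed = 5)
  expect_equal(nrow(empty$variants), 0)
  expect_length(map_variants_to_genes(empty$variants, empty$genes)$genes, 0)

  expect_error(simulate_gwas_fixture(s$truth, window_hits = 5, decoys = 0,
                                     seed = 1, chrom_length = 1e5),
               "too short")
})

test_that("fixture bundle round-trips bit-exactly with a complete manifest", {
  cfg <- sim_config(tissues = c("PFC", "CRE"), datasets_per_tissue = 2,
                    samples_per_dataset = 6, n_genes = 60,
                    planted_modules = data.frame(
                      module = 1:2, size = 10, home_tissue = c("PFC", "CRE"),
                      factor_mean = 3, factor_sd = 1,
                      loading_min = 0.8, loading_max = 1.2),
                    n_de_genes = 20, confounders = default_confounders(),
                    seed = 21)
  s <- simulate_study(cfg)
  out <- withr::local_tempdir()
  man <- write_fixture_bundle(s$datasets, s$truth, out)
  expect_equal(sum(grepl("^expr_", man$files)), 4)  # one per (tissue, dataset)
  back <- read_expression_tsv(file.path(out, "expr_PFC_1.tsv"))
  expect_identical(back, s$datasets$PFC_1$expr)
  gmt <- read_gmt(file.path(out, "planted_modules.gmt"))
  expect_length(gmt, 2)

  # determinism extends to the files: rewriting the same study matches
  out2 <- withr::local_tempdir()
  man2 <- write_fixture_bundle(simulate_study(cfg)$datasets, s$truth, out2)
  expect_identical(man$md5, man2$md5)
})
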