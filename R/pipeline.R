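#' Configure a full pipeline run
#'
#' Collects every stage threshold (defaults are the workflow's standard
#' values: DEG p < 0.05, confounder p < 0.05, module |r| > 0.6 & p < 0.05,
#' |GS| > 0.6 & |kME| > 0.8, RRA p < 0.05, +/-20 kb windows, 0.98 TOM
#' quantile, powers 1-20 scan or a fixed override), the two disease
#' simulation configs, and the root seed from which every stage seed is
#' derived.
#'
#' @param seed Root seed; stage seeds are derived deterministically from it.
#' @param sim_a,sim_b [sim_config()]s for the two disease cohorts. By default
#'   disease B lacks the fifth planted module, so one module is shared-absent
#'   across diseases and the consensus has something to reject.
#' @param deg_alpha,confounder_alpha,module_r,module_p,gs_min,kme_min,rra_alpha
#'   Stage thresholds.
#' @param covariates Covariate columns for the DE linear model.
#' @param confounders Metadata columns screened as confounders.
#' @param power Soft-threshold power when `power_mode = "fixed"`.
#' @param powers Scan range when `power_mode = "scan"`.
#' @param power_mode `"fixed"` (default) or `"scan"`.
#' @param cut_height,min_module_size,merge_cut Module detection parameters.
#' @param window GWAS window half-width (bp).
#' @param tom_quantile Quantile matched by the consensus TOM scaling.
#' @param gwas_hits,gwas_decoys Toy GWAS fixture geometry.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            sim_a = NULL, sim_b = NULL,
                            deg_alpha = 0.05, confounder_alpha = 0.05,
                            covariates = character(),
                            confounders = c("age", "sex", "ph"),
                            power = 8, powers = 1:20, power_mode = "fixed",
                            cut_height = 0.995, min_module_size = 30,
                            merge_cut = 0.25,
                            module_r = 0.6, module_p = 0.05,
                            gs_min = 0.6, kme_min = 0.8,
                            rra_alpha = 0.05, window = 20000,
                            tom_quantile = 0.98,
                            gwas_hits = 10, gwas_decoys = 10) {
  if (is.null(sim_a)) sim_a <- sim_config(seed = derive_seed(seed, 1))
  if (is.null(sim_b)) {
    pm <- default_planted_modules()
    sim_b <- sim_config(planted_modules = pm[pm$module != 5, ],
                        seed = derive_seed(seed, 2))
  }
  stopifnot(power_mode %in% c("fixed", "scan"),
            deg_alpha > 0, deg_alpha < 1, tom_quantile > 0, tom_quantile < 1,
            window >= 0, cut_height > 0, cut_height <= 1)
  structure(list(seed = seed, sim_a = sim_a, sim_b = sim_b,
                 deg_alpha = deg_alpha, confounder_alpha = confounder_alpha,
                 covariates = covariates, confounders = confounders,
                 power = power, powers = powers, power_mode = power_mode,
                 cut_height = cut_height, min_module_size = min_module_size,
                 merge_cut = merge_cut, module_r = module_r,
                 module_p = module_p, gs_min = gs_min, kme_min = kme_min,
                 rra_alpha = rra_alpha, window = window,
                 tom_quantile = tom_quantile,
                 gwas_hits = gwas_hits, gwas_decoys = gwas_decoys),
            class = "pipeline_config")
}

# one-disease arm: simulate -> DEG -> integrate -> network -> evidence -> calls
run_disease_arm <- function(cfg, sim_cfg, gwas_seed) {
  sim <- simulate_study(sim_cfg)
  datasets <- lapply(sim$datasets, log2_normalise)

  deg_tables <- lapply(datasets, differential_expression,
                       covariates = cfg$covariates, deg_alpha = cfg$deg_alpha)
  screens <- lapply(datasets, function(d) {
    confounder_screen(d, intersect(cfg$confounders, names(d$samples)),
                      confounder_alpha = cfg$confounder_alpha)
  })
  deg_sets <- mapply(function(d, s) select_degs(d, s), deg_tables, screens,
                     SIMPLIFY = FALSE)

  tissues <- unique(vapply(datasets, function(d) d$samples$tissue[1], character(1)))
  ds_tissue <- vapply(datasets, function(d) d$samples$tissue[1], character(1))
  merged <- list()
  for (t in tissues) {
    members <- names(datasets)[ds_tissue == t]
    m <- merge_tissue(datasets[members], deg_sets[members], case_only = TRUE)
    merged[[t]] <- remove_batch_effects(m)
  }
  combined <- combine_tissues(merged)

  power <- if (cfg$power_mode == "scan") {
    attr(scan_soft_thresholds(combined, powers = cfg$powers), "recommended")
  } else cfg$power
  net <- build_network(combined, beta = power)
  labels <- detect_modules(net, cut_height = cfg$cut_height,
                           min_module_size = cfg$min_module_size)
  mm <- merge_similar_modules(combined, labels, merge_cut = cfg$merge_cut)
  tis <- combined$samples$tissue
  mtc <- module_tissue_correlation(mm$ME, tis, r_min = cfg$module_r,
                                   p_max = cfg$module_p)
  gs <- gene_significance(combined, tis)
  screened <- screen_module_genes(mm$labels, mm$kME, gs, mtc,
                                  gs_min = cfg$gs_min, kme_min = cfg$kme_min)

  # RRA over the per-dataset rankings of each tissue; evidence = union
  rra_tables <- list()
  for (t in tissues) {
    members <- names(deg_tables)[ds_tissue == t]
    res <- robust_rank_aggregate(deg_tables[members], alpha = cfg$rra_alpha)
    res$tissue <- t
    rra_tables[[t]] <- res
  }
  rra_all <- do.call(rbind, rra_tables)
  rownames(rra_all) <- NULL
  rra_genes <- unique(rra_all$gene[rra_all$significant])

  gwas <- simulate_gwas_fixture(sim$truth, window_hits = cfg$gwas_hits,
                                decoys = cfg$gwas_decoys, seed = gwas_seed,
                                window = cfg$window)
  mapped <- map_variants_to_genes(dedupe_variants(gwas$variants), gwas$genes,
                                  window = cfg$window)

  # pipeline-level confounder exclusion: associated in every dataset of a tissue
  excluded <- character()
  for (t in tissues) {
    members <- names(screens)[ds_tissue == t]
    per_ds <- lapply(screens[members], `[[`, "excluded")
    excluded <- union(excluded, Reduce(intersect, per_ds))
  }

  calls <- call_tissue_specific_genes(screened, rra_genes, mapped$genes,
                                      confounder_excluded = excluded)
  list(sim = sim, datasets = datasets, deg_tables = deg_tables,
       deg_sets = deg_sets, screens = screens, merged = merged,
       combined = combined, power = power, net = net,
       labels = mm$labels, ME = mm$ME, kME = mm$kME, gs = gs,
       module_tissue = mtc, screened = screened, rra = rra_all,
       rra_genes = rra_genes, gwas = gwas, gwas_mapped = mapped,
       confounder_excluded = excluded, calls = calls,
       newick = tissue_dendrogram(combined, tis))
}

#' Run the full two-disease pipeline on synthetic cohorts
#'
#' Executes simulate -> per-dataset differential expression and confounder
#' screening -> per-tissue merging and batch adjustment -> cross-tissue
#' network and module detection -> per-disease tissue-specific module and
#' gene screens -> consensus (quantile-scaled TOMs, elementwise-minimum
#' consensus modules, sign-consistent correlation merge) -> robust rank
#' aggregation and toy GWAS mapping -> tissue-specific gene calls, shared
#' genes and over-representation, writing every documented table plus a
#' provenance manifest under `out_dir`. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with both disease arms (`a`, `b`), the
#'   consensus results and the output file manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  res <- tryCatch({
    stage <- "disease_a"
    a <- run_disease_arm(config, config$sim_a, derive_seed(config$seed, 3))
    stage <- "disease_b"
    b <- run_disease_arm(config, config$sim_b, derive_seed(config$seed, 4))

    stage <- "consensus"
    shared_genes <- intersect(rownames(a$combined$expr), rownames(b$combined$expr))
    if (length(shared_genes) < config$min_module_size) {
      stopf("only %d genes shared between the disease matrices", length(shared_genes))
    }
    xa <- a$combined$expr[shared_genes, , drop = FALSE]
    xb <- b$combined$expr[shared_genes, , drop = FALSE]
    net_a <- build_network(xa, beta = config$power)
    net_b <- build_network(xb, beta = config$power)
    # reference = the network whose high quantile is larger (scale up, not down)
    qa <- offdiag_quantile(net_a$tom, config$tom_quantile)
    qb <- offdiag_quantile(net_b$tom, config$tom_quantile)
    if (qa >= qb) {
      pair <- scale_tom(net_a$tom, net_b$tom, q = config$tom_quantile)
      ref_label <- "A"
    } else {
      pair <- scale_tom(net_b$tom, net_a$tom, q = config$tom_quantile)
      ref_label <- "B"
    }
    cons <- consensus_tom(pair)
    cons_labels <- detect_modules(1 - cons, cut_height = config$cut_height,
                                  min_module_size = config$min_module_size)
    eg_a <- compute_eigengenes(xa, cons_labels)
    eg_b <- compute_eigengenes(xb, cons_labels)
    cor_a <- module_tissue_correlation(eg_a$ME, a$combined$samples$tissue,
                                       r_min = config$module_r,
                                       p_max = config$module_p)
    cor_b <- module_tissue_correlation(eg_b$ME, b$combined$samples$tissue,
                                       r_min = config$module_r,
                                       p_max = config$module_p)
    cons_table <- merge_correlation_tables(cor_a, cor_b,
                                           r_min = config$module_r,
                                           p_max = config$module_p)

    stage <- "joint"
    shared_calls <- shared_tissue_genes(a$calls, b$calls)
    gmt <- split(a$sim$truth$genes[a$sim$truth$module_label > 0],
                 a$sim$truth$module_label[a$sim$truth$module_label > 0])
    names(gmt) <- sprintf("planted_module_%s", names(gmt))
    ora_a <- over_representation(a$calls$gene, gmt, rownames(a$combined$expr))
    ora_b <- over_representation(b$calls$gene, gmt, rownames(b$combined$expr))

    list(a = a, b = b,
         consensus = list(pair = pair, reference = ref_label, tom = cons,
                          labels = cons_labels, cor_a = cor_a, cor_b = cor_b,
                          table = cons_table),
         shared_calls = shared_calls, ora_a = ora_a, ora_b = ora_b)
  }, error = function(e) {
    failed <- file.path(out_dir, "failed")
    dir.create(failed, showWarnings = FALSE)
    writeLines(c(stage, conditionMessage(e)), file.path(failed, "stage.txt"))
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  stage <- "write"
  files <- write_pipeline_outputs(res, config, out_dir)
  res$files <- files
  invisible(res)
}

write_pipeline_outputs <- function(res, config, out_dir) {
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 17))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character()
  for (d in c("a", "b")) {
    arm <- res[[d]]
    files <- c(files,
      wt(data.frame(gene = names(arm$labels), module = arm$labels,
                    kME_own = ifelse(arm$labels > 0,
                                     arm$kME[cbind(seq_along(arm$labels),
                                                   match(sprintf("M%d", pmax(arm$labels, 1)),
                                                         colnames(arm$kME)))],
                                     NA_real_)),
         sprintf("modules_%s.tsv", d)),
      wt(arm$module_tissue, sprintf("module_tissue_cor_%s.tsv", d)),
      wt(arm$screened, sprintf("screened_genes_%s.tsv", d)),
      wt(arm$rra, sprintf("rra_%s.tsv", d)),
      wt(arm$gwas_mapped$hits, sprintf("gwas_hits_%s.tsv", d)),
      wt(arm$calls, sprintf("tissue_specific_genes_%s.tsv", d)))
    nwk <- file.path(out_dir, sprintf("tissues_%s.nwk", d))
    writeLines(arm$newick, nwk)
    files <- c(files, nwk)
  }
  files <- c(files,
             wt(res$consensus$table, "consensus_cor.tsv"),
             wt(data.frame(gene = names(res$consensus$labels),
                           module = res$consensus$labels), "consensus_modules.tsv"),
             wt(res$shared_calls, "shared_tissue_specific_genes.tsv"),
             wt(res$ora_a, "ora_a.tsv"), wt(res$ora_b, "ora_b.tsv"))
  scaling <- file.path(out_dir, "scaling_report.json")
  jsonlite::write_json(list(q = res$consensus$pair$q,
                            exponent = res$consensus$pair$exponent,
                            reference = res$consensus$reference,
                            quantile_reference = res$consensus$pair$quantile_reference,
                            quantile_target = res$consensus$pair$quantile_target),
                       scaling, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, scaling)

  prov <- file.path(out_dir, "provenance.json")
  cfg_echo <- config
  cfg_echo$sim_a <- unclass(cfg_echo$sim_a)
  cfg_echo$sim_b <- unclass(cfg_echo$sim_b)
  jsonlite::write_json(list(seed = config$seed,
                            config = unclass(cfg_echo),
                            files = basename(files),
                            md5 = as.list(stats::setNames(
                              unname(tools::md5sum(files)), basename(files)))),
                       prov, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(files, prov)
}
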