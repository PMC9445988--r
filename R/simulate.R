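#' Configure the synthetic multi-tissue study generator
#'
#' The generator emulates the design of an integrative multi-cohort
#' case/control transcriptomic study: several datasets (batches) per tissue,
#' planted tissue-restricted co-expression modules, case/control mean shifts
#' that are consistent across datasets, demographic confounder-driven genes,
#' additive/multiplicative batch effects, and Gaussian noise. Expression is
#' exported on the linear scale (`2^x`) so the pipeline's log2 step is
#' exercised.
#'
#' Each planted module is a latent-factor block: in its home tissue the
#' factor is active with mean `factor_mean` and sd `factor_sd`, and member
#' genes load on it with loadings drawn from `[loading_min, loading_max]`.
#' The nonzero activation mean makes module genes both co-varying and
#' elevated in the home tissue, which is what a tissue-specific expression
#' programme looks like to the downstream eigengene-tissue correlation.
#'
#' @param tissues Character vector of tissue labels.
#' @param datasets_per_tissue Number of independent datasets (batches) per tissue.
#' @param samples_per_dataset Samples per dataset, split evenly case/control.
#' @param n_genes Total number of genes.
#' @param planted_modules Data frame with columns `module`, `size`,
#'   `home_tissue`, `factor_mean`, `factor_sd`, `loading_min`, `loading_max`.
#' @param n_de_genes Number of case/control differentially expressed genes.
#' @param de_effect Standardised case-minus-control mean shift (units of
#'   `noise_sd`); the sign is drawn per gene and kept across tissues.
#' @param de_cover_modules If `TRUE` (default) the DE set contains all planted
#'   module genes (topped up with background genes): networks downstream are
#'   built on differential genes, so planted modules must live inside that space.
#' @param batch_shift_sd SD of the per-(gene, dataset) additive batch shift.
#' @param batch_scale_sd SD (log scale) of the multiplicative batch noise scale.
#' @param confounders Data frame with columns `name`, `type`
#'   (`"binary"`/`"continuous"`), `n_affected_genes`, `effect` (standardised).
#' @param noise_sd Residual Gaussian noise SD (log2 units).
#' @param baseline_mean,baseline_sd Per-gene baseline abundance distribution
#'   (log2 units).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tissues = c("PFC", "CRE", "PBMC", "WB"),
                       datasets_per_tissue = 3,
                       samples_per_dataset = 20,
                       n_genes = 450,
                       planted_modules = default_planted_modules(tissues),
                       n_de_genes = 300,
                       de_effect = 2,
                       de_cover_modules = TRUE,
                       batch_shift_sd = 1,
                       batch_scale_sd = 0.3,
                       confounders = default_confounders(),
                       noise_sd = 1,
                       baseline_mean = 7,
                       baseline_sd = 1.5,
                       seed = 1) {
  cfg <- list(tissues = as.character(tissues),
              datasets_per_tissue = datasets_per_tissue,
              samples_per_dataset = samples_per_dataset,
              n_genes = n_genes,
              planted_modules = as.data.frame(planted_modules),
              n_de_genes = n_de_genes,
              de_effect = de_effect,
              de_cover_modules = isTRUE(de_cover_modules),
              batch_shift_sd = batch_shift_sd,
              batch_scale_sd = batch_scale_sd,
              confounders = as.data.frame(confounders),
              noise_sd = noise_sd,
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_planted_modules <- function(tissues = c("PFC", "CRE", "PBMC", "WB")) {
  homes <- rep(tissues, length.out = 5)
  # modules 1-4: tissue-elevated programmes (activation mean > 0);
  # module 5: tissue-restricted covariance-only programme (mean 0, larger sd),
  # so the two modules sharing a home tissue stay statistically separable
  data.frame(module = 1:5, size = 50, home_tissue = homes,
             factor_mean = c(3, 3, 3, 3, 0), factor_sd = c(1, 1, 1, 1, 3),
             loading_min = 0.8, loading_max = 1.2,
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_confounders <- function() {
  data.frame(name = c("age", "sex"), type = c("continuous", "binary"),
             n_affected_genes = c(20, 20), effect = c(2, 2),
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  for (f in c("datasets_per_tissue", "samples_per_dataset", "n_genes")) {
    if (!is_count(cfg[[f]])) stopf("sim_config: `%s` must be a count >= 1", f)
  }
  if (length(cfg$tissues) < 1) stopf("sim_config: need >= 1 tissue")
  pm <- cfg$planted_modules
  if (nrow(pm)) {
    need <- c("module", "size", "home_tissue", "factor_mean", "factor_sd",
              "loading_min", "loading_max")
    miss <- setdiff(need, names(pm))
    if (length(miss)) stopf("planted_modules: missing column(s) %s",
                            paste(miss, collapse = ", "))
    if (sum(pm$size) > cfg$n_genes) {
      stopf("planted module sizes sum to %d > n_genes = %d",
            sum(pm$size), cfg$n_genes)
    }
    bad <- setdiff(pm$home_tissue, cfg$tissues)
    if (length(bad)) stopf("planted_modules: unknown home tissue(s) %s",
                           paste(bad, collapse = ", "))
    if (any(pm$factor_sd <= 0)) stopf("planted_modules: factor_sd must be > 0")
  }
  for (f in c("batch_shift_sd", "batch_scale_sd", "noise_sd", "baseline_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stopf("sim_config: `%s` must be > 0", f)
  }
  if (cfg$n_de_genes > cfg$n_genes) stopf("n_de_genes exceeds n_genes")
  invisible(cfg)
}

#' Simulate a multi-tissue, multi-dataset case/control study
#'
#' @param config A [sim_config()].
#' @return A list with `datasets` (named list of [expression_dataset()]
#'   objects on linear scale, one per tissue x dataset) and `truth`, a
#'   `GroundTruth` list recording every planting: `module_label` (integer per
#'   gene, 0 = background), `module_home`, `de_genes`/`de_sign`,
#'   `confounder_genes`, and `clean` (the batch-free log2 matrices, same
#'   noise realisation, for batch-correction oracles).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  pm <- cfg$planted_modules

  module_label <- stats::setNames(integer(cfg$n_genes), genes)
  loadings <- stats::setNames(numeric(cfg$n_genes), genes)
  pos <- 1L
  for (i in seq_len(nrow(pm))) {
    idx <- pos:(pos + pm$size[i] - 1L)
    module_label[idx] <- pm$module[i]
    loadings[idx] <- stats::runif(pm$size[i], pm$loading_min[i], pm$loading_max[i])
    pos <- pos + pm$size[i]
  }
  module_home <- stats::setNames(as.character(pm$home_tissue),
                                 as.character(pm$module))

  baseline <- stats::setNames(
    stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd), genes)

  module_genes <- genes[module_label > 0]
  background <- genes[module_label == 0]
  if (cfg$de_cover_modules) {
    extra <- max(0L, cfg$n_de_genes - length(module_genes))
    de_genes <- c(module_genes[seq_len(min(length(module_genes), cfg$n_de_genes))],
                  if (extra > 0) sample(background, min(extra, length(background))))
  } else {
    de_genes <- sample(genes, cfg$n_de_genes)
  }
  de_sign <- stats::setNames(sample(c(-1, 1), length(de_genes), replace = TRUE),
                             de_genes)

  conf <- cfg$confounders
  conf_pool <- setdiff(background, de_genes)
  confounder_genes <- list()
  for (i in seq_len(nrow(conf))) {
    k <- conf$n_affected_genes[i]
    if (k > length(conf_pool)) {
      warnf("confounder '%s': only %d unclaimed background genes available",
            conf$name[i], length(conf_pool))
      k <- length(conf_pool)
    }
    picked <- conf_pool[seq_len(k)]
    conf_pool <- setdiff(conf_pool, picked)
    confounder_genes[[conf$name[i]]] <- picked
  }

  n_case <- ceiling(cfg$samples_per_dataset / 2)
  n_ctrl <- cfg$samples_per_dataset - n_case

  datasets <- list()
  clean <- list()
  for (tissue in cfg$tissues) {
    # batch effects are deviations about each gene's mean across the tissue's
    # datasets (sum-to-zero location, geometric-mean-1 scale): the same
    # parameterisation the EB location/scale adjustment assumes
    k <- cfg$datasets_per_tissue
    shift_mat <- matrix(stats::rnorm(cfg$n_genes * k, 0, cfg$batch_shift_sd),
                        ncol = k)
    shift_mat <- shift_mat - rowMeans(shift_mat)
    lsc <- matrix(stats::rnorm(cfg$n_genes * k, 0, cfg$batch_scale_sd), ncol = k)
    scale_mat <- exp(lsc - rowMeans(lsc))
    for (d in seq_len(cfg$datasets_per_tissue)) {
      ds_name <- paste(tissue, d, sep = "_")
      ns <- cfg$samples_per_dataset
      sample_id <- sprintf("%s_s%02d", ds_name, seq_len(ns))
      status <- c(rep("case", n_case), rep("control", n_ctrl))
      meta <- data.frame(sample_id = sample_id, tissue = tissue,
                         status = status, batch = ds_name,
                         age = round(stats::runif(ns, 20, 80), 1),
                         sex = sample(c("F", "M"), ns, replace = TRUE),
                         ph = round(stats::runif(ns, 6.0, 7.5), 2),
                         stringsAsFactors = FALSE)

      signal <- matrix(baseline, nrow = cfg$n_genes, ncol = ns,
                       dimnames = list(genes, sample_id))
      for (i in seq_len(nrow(pm))) {
        if (pm$home_tissue[i] != tissue) next
        f <- pm$factor_mean[i] + pm$factor_sd[i] * stats::rnorm(ns)
        members <- module_label == pm$module[i]
        signal[members, ] <- signal[members, ] + outer(loadings[members], f)
      }
      is_case <- meta$status == "case"
      signal[de_genes, is_case] <- signal[de_genes, is_case] +
        de_sign * cfg$de_effect * cfg$noise_sd
      for (i in seq_len(nrow(conf))) {
        g <- confounder_genes[[conf$name[i]]]
        if (!length(g)) next
        if (conf$type[i] == "continuous") {
          z <- as.numeric(scale(meta[[conf$name[i]]]))
          signal[g, ] <- signal[g, ] +
            outer(rep(conf$effect[i] * cfg$noise_sd, length(g)), z)
        } else {
          lv <- meta[[conf$name[i]]] == sort(unique(meta[[conf$name[i]]]))[1]
          signal[g, lv] <- signal[g, lv] + conf$effect[i] * cfg$noise_sd
        }
      }

      noise <- matrix(stats::rnorm(cfg$n_genes * ns, 0, cfg$noise_sd),
                      nrow = cfg$n_genes)
      x <- signal + shift_mat[, d] + scale_mat[, d] * noise
      clean[[ds_name]] <- signal + noise
      datasets[[ds_name]] <- expression_dataset(2^x, meta)
    }
  }

  truth <- structure(list(genes = genes,
                          module_label = module_label,
                          module_home = module_home,
                          loadings = loadings,
                          baseline = baseline,
                          de_genes = de_genes,
                          de_sign = de_sign,
                          confounder_genes = confounder_genes,
                          clean = clean,
                          config = cfg),
                     class = "GroundTruth")
  list(datasets = datasets, truth = truth)
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d genes, %d planted modules, %d DE genes, %d confounder genes\n",
              length(x$genes), length(x$module_home), length(x$de_genes),
              length(unlist(x$confounder_genes))))
  invisible(x)
}

#' Simulate a toy GWAS variant table and gene annotation
#'
#' Lays the study's genes along a toy chromosome and emits a variant table in
#' which exactly `window_hits` variants fall within `window` bp of a
#' truth-selected gene (planted-module members first) while `decoys` fall
#' farther than `window` bp from every gene. One duplicated rsID is included
#' (when `window_hits >= 1`) to exercise recurring-variant merging.
#'
#' @param truth A `GroundTruth` from [simulate_study()].
#' @param window_hits,decoys Counts of in-window and out-of-window variants.
#' @param seed Integer seed.
#' @param window Window half-width in bp (default 20000).
#' @param gene_spacing,gene_length Toy geometry (bp); the gap between genes
#'   must exceed `2 * window` so decoys have somewhere to live.
#' @param chrom_length Optional chromosome length; an error is raised if the
#'   genes do not fit.
#' @return List with `variants` (data frame: rsid, chrom, pos, trait),
#'   `genes` (data frame in BED convention: chrom, start, end, gene;
#'   0-based half-open) and `hit_genes` (the intended in-window gene set).
#' @export
simulate_gwas_fixture <- function(truth, window_hits = 10, decoys = 10,
                                  seed = 1, window = 20000,
                                  gene_spacing = 100000, gene_length = 10000,
                                  chrom_length = NULL) {
  genes <- truth$genes
  n <- length(genes)
  if (window_hits > n) stopf("window_hits (%d) exceeds number of genes (%d)",
                             window_hits, n)
  if (gene_spacing - gene_length <= 2 * window + 2) {
    stopf("gene spacing leaves no room outside +/-%d bp windows", window)
  }
  needed <- n * gene_spacing + gene_spacing
  if (!is.null(chrom_length) && chrom_length < needed) {
    stopf("chromosome length %d too short for %d genes (need %d)",
          chrom_length, n, needed)
  }
  start0 <- as.integer((seq_len(n) - 1L) * gene_spacing + 45000)
  bed <- data.frame(chrom = "chrT", start = start0,
                    end = as.integer(start0 + gene_length),
                    gene = genes, stringsAsFactors = FALSE)

  with_seed(seed, {
    module_members <- genes[truth$module_label > 0]
    pool <- c(sample(module_members), sample(setdiff(genes, module_members)))
    hit_genes <- pool[seq_len(window_hits)]

    rows <- list()
    if (window_hits > 0) {
      hit_idx <- match(hit_genes, genes)
      # 5 kb upstream of the gene start: inside the +/-window by construction
      rows$hits <- data.frame(rsid = sprintf("rs%05d", hit_idx),
                              chrom = "chrT",
                              pos = as.integer(start0[hit_idx] + 1L - 5000L),
                              trait = "disease", stringsAsFactors = FALSE)
    }
    if (decoys > 0) {
      j <- seq_len(decoys)
      gap_after <- ((j - 1) %% n) + 1
      rows$decoys <- data.frame(rsid = sprintf("rs9%04d", j),
                                chrom = "chrT",
                                pos = as.integer(gap_after * gene_spacing + 1),
                                trait = "disease", stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, rows)
    if (is.null(variants)) {
      variants <- data.frame(rsid = character(), chrom = character(),
                             pos = integer(), trait = character(),
                             stringsAsFactors = FALSE)
    }
    if (window_hits >= 1) variants <- rbind(variants, variants[1, ])  # recurring rsID
    rownames(variants) <- NULL
    list(variants = variants, genes = bed, hit_genes = hit_genes)
  })
}

#' Write a simulated study to disk as a plain-text fixture bundle
#'
#' Emits one expression TSV (linear scale) and one metadata TSV per dataset,
#' the ground-truth tables, a GMT of the planted modules, optional GWAS
#' fixture files, and a JSON manifest listing every file with its MD5
#' checksum and the generator seed.
#'
#' @param datasets,truth Output of [simulate_study()].
#' @param out_dir Output directory (created if needed).
#' @param gwas Optional output of [simulate_gwas_fixture()].
#' @return The manifest, invisibly.
#' @export
write_fixture_bundle <- function(datasets, truth, out_dir, gwas = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(datasets)) {
    fe <- file.path(out_dir, sprintf("expr_%s.tsv", nm))
    fm <- file.path(out_dir, sprintf("meta_%s.tsv", nm))
    write_expression_tsv(datasets[[nm]]$expr, fe)
    write_sample_metadata(datasets[[nm]]$samples, fm)
    files <- c(files, fe, fm)
  }
  ft <- file.path(out_dir, "truth_modules.tsv")
  utils::write.table(
    data.frame(gene = truth$genes, module = truth$module_label,
               home_tissue = ifelse(truth$module_label > 0,
                                    truth$module_home[as.character(truth$module_label)],
                                    NA_character_)),
    ft, sep = "\t", quote = FALSE, row.names = FALSE)
  fd <- file.path(out_dir, "truth_de.tsv")
  utils::write.table(data.frame(gene = truth$de_genes,
                                sign = truth$de_sign[truth$de_genes]),
                     fd, sep = "\t", quote = FALSE, row.names = FALSE)
  fc <- file.path(out_dir, "truth_confounders.tsv")
  cg <- truth$confounder_genes
  utils::write.table(
    data.frame(gene = unlist(cg, use.names = FALSE),
               confounder = rep(names(cg), lengths(cg))),
    fc, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, ft, fd, fc)

  fg <- file.path(out_dir, "planted_modules.gmt")
  sets <- split(truth$genes[truth$module_label > 0],
                truth$module_label[truth$module_label > 0])
  names(sets) <- sprintf("module_%s", names(sets))
  write_gmt(sets, fg)
  files <- c(files, fg)

  if (!is.null(gwas)) {
    fv <- file.path(out_dir, "variants.tsv")
    utils::write.table(gwas$variants, fv, sep = "\t", quote = FALSE, row.names = FALSE)
    fb <- file.path(out_dir, "genes.bed")
    utils::write.table(gwas$genes, fb, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, fv, fb)
  }

  manifest <- list(seed = truth$config$seed,
                   n_genes = length(truth$genes),
                   files = basename(files),
                   md5 = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
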