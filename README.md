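# tissuemod

Integrative tissue-specificity analysis for multi-cohort case/control
transcriptomics, as used in mood-disorder studies that span brain regions
(PFC, ACC, AMY, CRE, HPC, STR) and blood (PBMC, WB). The package answers:
*which co-expression programmes are specific to a tissue in patients, and
which of their genes carry independent disease evidence?*

The workflow, each stage a tested package function:

1. **Differential expression per dataset** — per-gene OLS of log2 expression
   on case/control status (equal to the pooled t-test without covariates),
   DEGs at the loose `p < 0.05`, plus a demographic confounder screen
   (age/sex/pH; t-test or Pearson, `p < 0.05`).
2. **Integration** — same-tissue datasets merged over their DEG union (case
   samples only), batch effects removed by the parametric empirical-Bayes
   location/scale model (per-batch means `γ` and variances `δ²` shrunk
   toward moment-matched normal / inverse-gamma priors).
3. **Network** — unsigned adjacency `a_ij = |cor(x_i, x_j)|^β` (soft power
   from a scale-free-fit scan over 1–20 or a fixed override), topological
   overlap `T_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   average-linkage clustering of `1 − T` with a fixed-height cut, module
   eigengenes (first PC), kME and per-tissue gene significance GS. A module
   is tissue-specific when `|r| > 0.6` and `p < 0.05` against the tissue
   indicator; genes are screened at `|GS| > 0.6` and `|kME| > 0.8`.
4. **Consensus across diseases** — the target TOM is raised elementwise to
   `log q_ref / log q_tgt` so both 98th percentiles match, the consensus TOM
   is the elementwise minimum, and the two module–tissue correlation tables
   merge under the sign-consistency rule (same sign: keep the
   smaller-magnitude `r` and larger `p`; otherwise `NA`).
5. **Evidence** — robust rank aggregation of per-dataset logFC rankings
   (`ρ` = min Beta(k, n−k+1) order-statistic CDF, corrected
   `p = min(1, ρ·n)`), and ±20 kb window mapping of GWAS variants to gene
   intervals after merging recurring rsIDs.
6. **Tissue-specific genes** — screened module genes present in the RRA or
   GWAS evidence, minus confounder-excluded genes; shared calls across
   diseases are intersected on (gene, tissue). A generic hypergeometric
   over-representation test against user GMT collections annotates the
   lists.

A seeded synthetic-data generator (`sim_config()`, `simulate_study()`)
emulates the study design — planted tissue-restricted modules, consistent
case/control shifts, additive/multiplicative batch effects, confounder
genes — with full ground truth, so every stage is verifiable at desk scale.

## Worked example: the analysis workflow

The `analysis/` directory holds the numbered drivers; run them in order
from the repository root:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

Outputs accumulate under `results/`. A run with the default seed prints,
among other things:

```
cohort A: 12 datasets, 450 genes, 5 planted modules -> results/data/a
cohort A WB: 307 genes x 30 case samples; median batch F 5.90 -> 0.104
cohort A: 257 genes, 4 modules, 4 tissue-specific module calls
  (M3~CRE r=0.94, M2~PBMC r=0.95, M1~PFC r=0.94, M4~WB r=0.93); 128 screened genes
consensus modules: 4; consistent flagged module-tissue pairs: 4
cohort A: robust DEGs per tissue: CRE=145  PBMC=138  PFC=148  WB=131
cohort A: 116 tissue-specific genes (CRE=27  PBMC=23  PFC=33  WB=33)
shared across cohorts (gene x tissue): 86
cohort A calls in the right planted home tissue: 100.0%
```

Reading this: the batch model collapses the per-gene batch F statistic from
~6 to ~0.1; the network recovers one module per planted tissue-elevated
programme and flags each for its home tissue with `r ≈ 0.93–0.95`; robust
rank aggregation keeps the consistently top-ranked differential genes; and
every final tissue-specific call lands in the correct planted home tissue.
The same pipeline is available as one call:

```r
library(tissuemod)
res <- run_pipeline(pipeline_config(seed = 1), "results/run")
nrow(res$a$calls)          # tissue-specific genes, disease A
res$consensus$table        # sign-consistent consensus module-tissue table
```

Reruns with the same seed are byte-identical (checksums in
`provenance.json`).

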