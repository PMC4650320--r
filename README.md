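# AIRseq

Comparative analysis of the LPS pro-inflammatory and IL-10
anti-inflammatory (AIR) transcriptional programs across myeloid cell
types — macrophages, neutrophils, splenic dendritic cells, mast cells and
eosinophils — from gene-level RNA-seq count matrices to classified gene
sets, promoter CpG statistics and motif enrichment.

The package is aimed at computational immunologists who want to ask, on
their own count data or on fully controlled simulations: which genes does
LPS induce in each cell type, which of those does IL-10 pre-treatment
suppress (the AIR), how much of that suppression is shared between cell
types, and what distinguishes AIR from not-AIR promoters?

## The model

The experimental design is 5 cell types x 4 treatments (ctrl, IL-10, LPS,
IL-10 then LPS) x biological replicates.

**Differential expression.** Counts are modeled as negative binomial,
`K_gs ~ NB(s_s * mu_g, alpha_g)` with `Var = mu + alpha * mu^2`.  Size
factors `s_s` come from median-of-ratios normalization (rescaled to
geometric mean 1).  Per-gene dispersion is a pooled within-group
method-of-moments estimate, `alpha = max(0, (s^2 - m) / m^2)`, made
conservative by taking the maximum of the raw value and a fitted
mean-dispersion trend `alpha(mu) = a0 + a1/mu`.  Each two-group contrast
(LPS vs ctrl, IL-10 vs ctrl, IL-10+LPS vs LPS, within cell type) is
tested by a Wald test on the difference of log group means with
NB-propagated variance (an exact conditional binomial test replaces it
for small counts at zero dispersion), followed by Benjamini-Hochberg
correction; genes change when q < 0.1.

**Regulation calls and the relaxation rule.** Because NB testing at 2
replicates is conservative, a gene significant in one cell type is marked
regulated in any other cell type where its fold-change is > 1.5 in the
same direction, even without significance there.

**AIR classification.** Among each cell type's LPS-up genes, AIR genes
are those whose expression declines at least 2-fold (inclusive) from the
LPS to the IL-10+LPS condition, measured on normalized condition means
with a pseudocount; the rest are not-AIR.  Eosinophils, which do not
mount an IL-10 response, are excluded.  Per-cell-type sets are combined
into exclusive overlap categories (unique, exactly-2, ..., all-k), and
cell-type-specific AIR sets are obtained by removing every gene AIR in 2
or more cell types.

**Promoters.** The promoter is the window [TSS - 450 bp, TSS + 50 bp) in
gene orientation.  CG dinucleotides are counted per window and AIR vs
not-AIR distributions are compared by a two-sided Mann-Whitney U test.
Motif enrichment scores each promoter with its best log2-odds PWM hit
(both strands, normalized to [0, 1] by the PWM's attainable extremes) and
compares a gene set's mean score against the full promoter background,
`z = (mean_fg - mean_bg) / (sd_bg / sqrt(n_fg))`, BH-corrected across the
library.

**QC and reduction.** Replicate Pearson correlations and pairwise R^2
clustering on log2(normalized + 1) expression, plus PCA with per-component
point-biserial correlation against the LPS and IL-10 treatment
indicators to locate (or fail to locate) a treatment axis.

**Simulator.** All of the above is exercised by a generator that plants
LPS-common, LPS-cell-type-specific, AIR, IL-10-induced and cell-identity
modules into NB counts, and emits matched promoter sequences (CpG-poor
AIR promoters, embedded motif consensus), a PWM library and a
cytokine-family table, with full ground truth.

## Worked example

```r
library(AIRseq)
cfg <- simulation_config(n_genes = 1000, seed = 42)
sim <- simulate_counts(cfg)              # counts + ground truth
de  <- run_de(sim$counts)                # all contrasts, all cell types
reg <- call_regulation(de)
lps_up <- regulation_sets(reg, "LPS_vs_ctrl", "up")
expr <- condition_means(sim$counts, attr(de, "size_factors"))
part <- classify_air(lps_up, expr, responsive = sim$truth$il10_responsive)
print(part)
#> macrophage   AIR   36  not-AIR   88  (29% AIR)
#> neutrophil   AIR   38  not-AIR   89  (30% AIR)
#> sDC          AIR   41  not-AIR   87  (32% AIR)
#> mast         AIR   37  not-AIR   89  (29% AIR)
```

Each responsive cell type's LPS-induced genes split into an AIR fraction
near the planted 30%.  Promoter CpG statistics on the matched simulated
promoters:

```r
prom <- simulate_promoters(sim$truth, cfg)
win  <- extract_windows(prom)
cpg_compare_partition(part, win)[, c("cell_type", "n_air", "mean_air",
                                     "mean_not_air", "p", "sig_01")]
#>    cell_type n_air mean_air mean_not_air           p sig_01
#> 1 macrophage    36 19.88889     26.90909 0.202603863  FALSE
#> 2 neutrophil    38 18.97368     27.65169 0.006605746   TRUE
#> 3        sDC    41 20.41463     27.04598 0.160233427  FALSE
#> 4       mast    37 20.21622     26.83146 0.202444441  FALSE
```

AIR promoters carry fewer CG dinucleotides per 500 bp window than
not-AIR promoters (the planted CpG-poor class), reaching significance
where the sampled sets are least diluted.  Finally:

```r
pca_treatment_axis(sim$counts)
#> pca_result: 40 samples, 40 components
#> LPS axis: PC1  IL-10 axis: PC6
```

The `run_pipeline()` orchestrator runs all stages from one configuration
into an output directory (TSV tables, JSON summaries, a run report with
truth-vs-called confusion matrices), deterministically per seed.

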