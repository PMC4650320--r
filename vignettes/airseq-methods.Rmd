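---
title: "AIRseq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AIRseq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AIRseq)
```

AIRseq analyzes how myeloid cells respond to the endotoxin LPS and how
IL-10 pre-treatment suppresses part of that response (the
anti-inflammatory response, AIR).  This vignette is the package's
account of its statistical machinery: the models, every tunable
parameter that matters, what the simulator does and does not emulate,
and the choices made where the design was genuinely open.

## The count model and the DE core

Counts are treated as negative binomial, `Var = mu + alpha * mu^2`.
The DE core is deliberately a simple, fully specified two-group
machinery rather than a general GLM:

* **Size factors** (`size_factors()`): median across genes of the ratio
  of a sample's count to the gene's geometric mean, over genes positive
  in every sample, rescaled to geometric mean 1 (so a k-fold global
  scaling of all counts leaves fold-changes untouched).  When no gene is
  positive everywhere, each sample falls back to its own positive genes;
  a sample with no positive counts is an error.
* **Dispersion** (`estimate_dispersion()`): per gene, the pooled
  within-group method-of-moments estimate
  `alpha = max(0, (s^2 - m)/m^2)`, where `s^2` pools within-group
  variances over all design groups with at least two replicates and `m`
  averages the group means.  A trend `alpha(mu) = a0 + a1/mu` is fitted
  by least squares over genes with base mean at or above 5 normalized
  counts (below that, moment estimates are dominated by Poisson noise),
  with coefficients clamped at 0.  The working dispersion is
  `max(raw, trend)` — the conservative sharing rule: genes whose
  scatter happens to look large are never given the benefit of the
  doubt.  The cost of that rule is a few points of sensitivity when only
  one two-group contrast contributes (4 residual degrees of freedom at
  n = 3); dispersion should therefore be estimated from the full design,
  which is what `run_de()` does.
* **Testing** (`test_contrast()`): a Wald test of the difference of log
  group means, with `Var(log mean) ~ Var(mean)/mean^2` and
  `Var(mean) = mu * sum(1/s_s)/n^2 + alpha * mu^2 / n` propagated from
  the working dispersion.  Group means are floored at half a normalized
  count inside the variance/log computation so genes observed in only
  one group remain testable.  When the working dispersion is zero and
  the two-group total is at most 50 counts, the normal approximation is
  replaced by the exact conditional test (counts in group B given the
  total are binomial with probability `S_B/(S_A+S_B)` of the size-factor
  sums).  Genes with no counts anywhere are flagged untested with
  `p = 1` and `log2fc = 0`, and excluded from the BH denominator.
* **Fold-changes** are reported as
  `log2((mean_B + 1)/(mean_A + 1))` — the pseudocount (1 normalized
  count) keeps them finite and is *not* used in testing.

The three contrasts are fixed by the design: LPS vs ctrl (the
pro-inflammatory program), IL-10 vs ctrl (the IL-10 program), and
IL-10+LPS vs LPS (AIR suppression), always within cell type.

## Thresholds and their boundaries

All thresholds live in `analysis_params()`:

| parameter | default | unit | role |
|---|---|---|---|
| `q_threshold` | 0.1 | probability | BH significance for DE calls |
| `relax_fc` | 1.5 | linear FC | cross-cell-type relaxation, **strict** `>` |
| `air_fc` | 2 | linear FC | AIR decline rule, **inclusive** `>=` |
| `promoter_upstream/downstream` | 450 / 50 | bp | promoter window |
| `cpg_ref_freq` | 0.75 | CG per window | display reference only |
| `pseudocount` | 1 | normalized counts | fold-change ratios |
| `mwu_alpha` | 0.05, 0.01 | probability | rank-test flags |
| `expression_floor` | 5 | normalized counts | "expressed" gene filter |
| `axis_cor_threshold` | 0.7 | correlation | treatment-axis call |

The inequality directions are deliberate: the relaxation rule marks a
gene regulated in a cell type only when its fold-change is strictly
greater than 1.5 (a gene at exactly 1.5-fold stays unchanged), whereas
the AIR rule ("declining at least 2-fold") and the known-target marking
("at least 1.5-fold") are inclusive.  The relaxation rule also requires
a significant anchor in another cell type *in the same direction*; a
strong fold-change with no anchor anywhere is never promoted.

AIR membership is decided by the ratio of normalized condition means
with pseudocount, `(mean_LPS + 1)/(mean_IL10_LPS + 1) >= 2`, not by a
second significance test: the classification is a fold-change rule by
definition, and coupling it to test power at n = 2 would conflate two
different questions.  Cell types flagged non-IL-10-responsive
(eosinophils by default, which show no STAT3 activation and no cytokine
suppression) are excluded from AIR analysis entirely rather than
reported as empty sets.

The IL-10-induced gene sets use the IL-10 vs ctrl contrast.  The
alternative reading (IL-10+LPS vs LPS) measures suppression-context
induction and is answerable through `call_regulation()` on that
contrast; the package treats "up-regulated by IL-10" as the
IL-10-alone contrast because that is what the phrase denotes
operationally.

## Promoter windows, CpG and motifs

The promoter window is `[TSS - 450, TSS + 50)`, 0-based half-open, in
gene orientation: for `-` genes the reverse complement of the mirrored
interval.  This makes the window exactly 500 bp with the TSS at offset
450, consistent with "450 bp upstream and 50 bp downstream".  Windows
that would run off a contig are flagged truncated and excluded from all
statistics (a partial window would bias the CG count downward).

CG dinucleotides are counted on the gene-oriented strand only; since CG
is its own reverse complement at the dinucleotide level the choice is
inconsequential (a property the test suite verifies by brute force).
Pairs containing N never count, and N-containing subsequences are
likewise skipped during motif scanning.

Motif enrichment is a best-hit statistic: each promoter's score for a
PWM is the maximum over all offsets and both strands of the log2-odds
sum `sum_j log2(p_jb / q_b)`, with matrix probabilities floored at
`1e-3` (so an observed-zero base costs about 8 bits rather than
infinity), normalized to [0, 1] by the PWM's attainable extremes.  A
PWM whose extremes coincide (the uniform matrix under a uniform
background) is scored 0.5 by convention and is degenerate for
enrichment.  The set-level statistic compares the foreground mean score
with the background of *all* analyzed promoters,
`z = (mean_fg - mean_bg)/(sd_bg/sqrt(n_fg))`, one-sided upper normal
p-value, BH across the library.  The background mean is reported per
PWM precisely so that ubiquitous TSS-proximal motifs are visibly
uninformative (a saturated motif has a high background mean and little
room for enrichment); no special correction is applied.  Foregrounds
below 5 scorable promoters are refused; `sd_bg = 0` yields `p = 1` with
a degenerate flag.

Rank tests use `stats::wilcox.test`: exact for small untied samples
(the 3-vs-3 oracle case gives `U = 0`, `p = 0.1`), normal approximation
with tie and continuity correction otherwise.  Groups below 3
observations report `p = NA` rather than an untrustworthy number.

## QC and the treatment axis

All correlation and PCA work happens on `log2(normalized + 1)`
expression; the transformation is the conventional variance-compressing
choice and is recorded here because nothing downstream is invariant to
it.  PCA runs on centered values over the expressed gene set
(`expression_floor`), signs fixed so each component's largest-magnitude
loading is positive (making scores reproducible under gene reordering).
For every component the point-biserial correlation with the LPS
indicator (treatment LPS or IL-10+LPS) and the IL-10 indicator is
reported; the LPS axis is the lowest-index component with absolute
correlation above 0.7.  No IL-10 axis is forced — its absence is an
observable outcome, and in default simulations the IL-10 indicator
typically associates only with late components.

## What the simulator emulates — and what it does not

`simulation_config()` defaults encode the study design: 5 cell types, 4
treatments, 2 biological replicates, NB counts with a single dispersion
`alpha = 0.1`, baselines log-uniform on [20, 200], log-normal library
size factors (sdlog 0.15).  Planted structure: 10% of genes LPS-induced
in every cell type (6-fold), 10% split into disjoint per-cell-type LPS
modules, 30% of each cell type's LPS-up genes suppressed 4-fold by
IL-10 (the AIR; myeloid cells suppress roughly 15-34% of their
LPS-induced genes, motivating the 30% default), 5% IL-10-induced 4-fold, and 15% cell-identity genes (8-fold
elevated baseline in one cell type) so that sample-level structure is
dominated by cell identity where the design says it should be.
Eosinophils have IL-10 effects disabled.  `air_mode` switches between
largely disjoint per-cell-type AIR sets ("specific", the default, the
structure actually observed) and one shared AIR set ("shared", the
counterfactual used to test that the overlap analysis can tell the two
apart).  Effect sizes are calibration choices — the study reports
observed fold-changes, not generative parameters.

Promoters are sampled as 250 independent dinucleotide blocks with a
class-specific CG-block probability (poor 0.01, rich 0.15), giving
CpG-poor windows about 20 CG dinucleotides per 500 bp and rich ones
about 40-50 (cross-block CG occurrences add a common baseline).  AIR
genes are always CpG-poor; other genes are rich with probability 0.6,
in line with the majority of mammalian promoters being CpG-island
associated.  AIR-gene promoters carry one embedded copy of an NF-kB-like
consensus decamer (GGGACTTTCC) at a uniform random offset; the PWM
library holds the sharp planted matrix (about 1.4 bits per position)
plus flat-Dirichlet decoys.

Not emulated: GC-content bias (and hence GC normalization — size
factors are depth-only), per-gene dispersion variation, batch effects,
read-level artifacts, transcript-level multiplicity (the package
operates on one gene id space throughout), linkage between promoter
sequence and expression noise, and real motif syntax (one planted
consensus, independent decoys).  Passing tests therefore demonstrate
that the statistical machinery recovers planted structure of realistic
magnitude under clean NB sampling — not that any particular biological
dataset will show the same effect sizes.

## Determinism and the orchestrator

Every stochastic stage derives its own substream seed from the single
configuration seed plus a stable hash of the stage name, so toggling
one stage never shifts another's randomness, and a rerun with an
identical configuration is byte-identical (the run log, which records
wall times, is the one deliberately non-reproducible file).  The
orchestrator `run_pipeline()` / `run_report()` is the package's
programmatic entry point — stages simulate, de, classify, cpg, motifs,
families, qc, report — writing TSV tables and JSON summaries stamped
with the seed and a configuration hash; for simulated runs the report
includes truth-versus-called AIR confusion matrices.

## Problem sizes used by the test suite

The suite's statistical checks run at deliberately modest sizes chosen
to keep sampling error well below the asserted margins: null
calibration at 5000 genes x 5 seeds; power benchmarks at 2000 genes in
a 3-cell-type ctrl/LPS design (dispersion pooled experiment-wide, as
`run_de()` operates); AIR recovery on full 2000-gene study-design
defaults across 5 seeds; promoter statistics at 150 promoters per
group with 200 label permutations; motif exactness on 200 random
PWM-sequence pairs and null calibration over 20 resampled foregrounds.

## Known limitations

The DE core is a two-group machinery: no multi-factor designs, no
interaction terms, no fold-change shrinkage.  The conservative
dispersion rule costs sensitivity in minimal designs (use the full
design for estimation).  The enrichment z-statistic treats promoter
scores as exchangeable and the foreground as sampled with replacement
from the background; for foregrounds that are a large fraction of the
background the test is conservative.  Family labels are an input — the
package ships no curated cytokine catalogue.  The Mann-Whitney normal
approximation is used whenever ties are present, which with integer CG
counts is essentially always at realistic sizes.
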