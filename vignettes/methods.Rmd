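---
title: "Stage-resolved ceRNA network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved ceRNA network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Under the competing endogenous RNA (ceRNA) hypothesis, lncRNAs and mRNAs
co-regulate each other by competing for a shared pool of miRNAs: a miRNA
bound to one transcript cannot repress another. The observable footprint of
this competition is a *negative* expression correlation between a miRNA and
the targets it represses. `ceRNAstage` operationalises a stage-resolved
version of this analysis for a staged tumour cohort (the motivating setting
is lung adenocarcinoma with TNM stages I-IV plus normal tissue): one ceRNA
network is built per stage, the networks are compared across stages, and the
miRNAs that organise them are screened as survival biomarkers.

The pipeline is a fixed sequence of filters:

1. **Differential expression** per stage versus normal: a gene passes when
   `|log2FC| >= 1` (inclusive) *and* its Welch two-sample p-value `< 0.05`
   (strict). `log2FC` is the difference of mean `log2(x + 1)` expression.
2. **Interaction matching**: differentially expressed miRNAs are matched to
   differentially expressed lncRNA/mRNA targets through a curated
   interaction table; pairs absent from the table can never become edges.
3. **Negative-correlation selection**: a matched pair becomes an edge only
   when its Pearson correlation, computed on `log2(x + 1)` expression over
   the tumour samples of the stage, is strictly below `-0.1`.
4. **Partition**: miRNAs present in *all four* stage networks induce the
   common network (CCEN); miRNAs present in *exactly one* induce that
   stage's unique network (UCEN); miRNAs in two or three stages form a
   "shared" middle class that belongs to neither compartment (mirroring the
   arithmetic implied by the discarded middle class in the motivating
   study's counts).
5. **Enrichment**: hypergeometric over-representation of the mRNA
   compartments against user-supplied gene sets, plus the enrichment
   efficiency `eta = -log10(p) / list size`.
6. **Survival screen**: per miRNA and stage, a median expression split
   compared with the unweighted log-rank test; "pan-stage" = significant in
   every evaluable stage, "stage-specific:s" = significant in stage s only.

Every network emitted is *doubly bipartite*: edges run only between miRNAs
and lncRNAs or miRNAs and mRNAs, so any lncRNA-mRNA relationship is mediated
by a shared miRNA. `validate_doubly_bipartite()` asserts this on every
construction path.

## The statistics, in the package's notation

**Hypergeometric over-representation.** For a background of `N` genes of
which `M` are annotated to a term, and a query list of `n` genes with `k`
annotated, the upper-tail p-value is

$$p = P(X \ge k) = \sum_{i=k}^{\min(M,n)}
\frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$

computed in log space via `lchoose` and clamped to `(0, 1]`. Terms with
`k = 0` have `p = 1` by the empty-sum convention and are omitted from
output. No multiple-testing correction enters the analysis path (a
Benjamini-Hochberg column is emitted for users, nothing consumes it): the
raw-p reporting matches the practice this pipeline reproduces and is a
documented limitation, not a recommendation.

**Enrichment efficiency.** `eta = -log10(p) / s` where `s` is the size of
the analysed gene list. The defining property is exact scaling,
`eta(p, c*s) = eta(p, s) / c`: a list half the size carrying the same
annotation signal is twice as efficient. The normalising `s` is taken as the
*query-list* size, not the background size — dividing by a shared background
constant would make the cross-list comparison a pure `-log10(p)` ranking and
the statistic vacuous; `eta_norm = "background_size"` restores the other
reading for users who want it.

**Kaplan-Meier.** The product-limit estimate
`S(t_i) = S(t_{i-1}) (1 - d_i / n_i)` with `n_i` at risk just before `t_i`
and `d_i` deaths at `t_i`; censorings shrink the risk set without a step,
and at tied times deaths are processed before censorings (both count in the
risk set at that time). This matches `survival::survfit` to machine
precision, which the test suite asserts on random datasets.

**Log-rank.** Unweighted: at each distinct death time the observed deaths in
group A are compared with the hypergeometric expectation
`E = d n_A / n`, with variance `d (n_A/n)(n_B/n)(n-d)/(n-1)`, and
`(sum(O-E))^2 / sum(V)` is referred to chi-square with 1 df.

## The synthetic world

The motivating study's inputs (a full TCGA cohort plus three curated
interaction databases) are not desk-reproducible, so the package carries a
seeded generator whose *structure* matches what the analysis assumes, with a
ground-truth ledger for recovery testing. What it emulates, and how:

* **Expression** is log-normal: `2^(mu_class + effect + N(0, sd)) - 1`,
  clipped at zero. Class baselines (4/6/8 log2 units for lncRNA/miRNA/mRNA)
  are set high enough that clipping is negligible, so the pipeline's
  `log2(x+1)` transform recovers the latent log2 values and planted
  correlations survive the round trip.
* **Planted triples** (lncRNA, miRNA, mRNA) receive a `planted_log2fc`
  up-shift on the miRNA and down-shift on both targets in the tumour samples
  of their scope — either all four stages (CCEN material) or exactly one
  (UCEN material). Each target additionally tracks the miRNA's noise with
  slope −1 plus independent noise of standard deviation
  `sd * sqrt(1/rho^2 - 1)`, which makes the population correlation exactly
  `planted_correlation`. This mirrors the repression mechanism the
  negative-correlation filter assumes.
* **The interaction table** contains every planted pair plus `db_decoy_pairs`
  random miRNA-target pairs with no correlation structure — the decoys are
  what the correlation filter must reject.
* **Annotation**: `n_terms` gene sets of `term_size` mRNAs; the first few are
  packed with planted target mRNAs so enrichment recovery is testable.
* **Survival** is exponential with hazard
  `base_hazard * exp(beta * z)`, where `z` is the standardised expression of
  each prognostic miRNA over the samples its scope covers, and `beta` is
  `hazard_coefficient`. Censoring is independent uniform on `(0, b)` with
  `b` solved (by `uniroot`) so the expected censoring fraction under the
  baseline hazard equals `censoring_rate`.

Defaults are a deliberately scaled-down stand-in for a staged cancer cohort:
150/80/400 genes per class, 50 normal + 60 samples per stage, effect size 2
log2 units, planted correlation −0.6, noise SD 1, base hazard
5e-4 per day (median survival ≈ 1400 days), 30% censoring. The real cohort
is roughly two orders of magnitude larger in gene count and has very
unbalanced stages (stage IV cohorts are small); the generator keeps stages
balanced because nothing in the method depends on imbalance, and small
unbalanced stages only add Monte-Carlo noise to tests.

What the generator does **not** emulate — and therefore what a green test
does not establish: negative-binomial count noise and library-size
artefacts, batch effects, correlated co-regulation beyond the planted
pairs, competing risks, and real interaction-database bias. A pipeline that
recovers planted structure here can still be misled by those features on
real data.

## Numerical and procedural choices

* **Welch t rather than a moderated t.** The motivating analysis names a
  variance-moderation package but specifies only a t-statistic; the plain
  Welch test is self-contained and oracle-checkable against the textbook
  formula. With ≥ 15 samples per group (all defaults here) moderation
  changes little; at very small n the moderated test would be more powerful.
* **Boundary conventions.** `|log2FC| >= 1` keeps ties at the threshold;
  `p < 0.05` and `r < -0.1` are strict. Degenerate genes (any group with
  < 2 samples, or both groups constant) get `p = 1` with a flag and are
  retained, never silently dropped; constant expression vectors make a
  pair's correlation undefined and the pair is excluded with a counted
  warning.
* **Correlation sample scope.** Tumour samples of the stage only, by
  default. Including normals (`"tumor_plus_normal"`) inflates negative
  correlations for any anti-regulated DE pair (the two groups separate along
  both axes) and would make the −0.1 filter nearly vacuous for DE genes;
  scoping to the stage's tumour samples measures co-variation where the
  ceRNA competition is claimed to act. The scope is configurable and echoed
  in the run manifest.
* **CCEN edge inheritance.** The common network takes the *union* over
  stages of edges incident to the common miRNAs, collapsing duplicates to
  the most negative correlation; the union keeps the CCEN stage-agnostic,
  which is the point of that compartment.
* **Median split, ties to low.** The high/low survival grouping is a median
  split with the median itself assigned to "low" (deterministic, balanced to
  within one). Mean and quantile splits are available; classification at
  `alpha = 0.05` is advisory and the full p-value matrix is the primary
  output, since borderline values are scientifically interesting.
* **Stage-specific classification is structurally noisy.** "Significant in
  exactly one stage" breaks whenever any null stage crosses `alpha` by
  chance — probability `1 - (1-alpha)^3 ≈ 14%` with three null stages even
  at infinite power. The recovery tests therefore assert the pooled
  correct-classification rate over planted pan-stage and single-stage
  miRNAs together (measured ≈ 0.94 at 150 subjects/stage, hazard
  coefficient 0.8), and the per-kind decomposition (pan ≈ 1.00,
  single-stage ≈ 0.88) is reported here rather than hidden.
* **Determinism.** One seed in `sim_config` drives every draw in a fixed
  order, so equal configurations produce byte-identical fixtures; numeric
  TSVs are written with 17 significant digits so doubles round-trip
  bit-for-bit.

## Known limitations

* Raw p-values throughout (DE filter and enrichment), matching the
  reproduced practice; with thousands of genes the DE sets contain an
  expected 5% of null genes at the p-cut alone — the fold-change condition,
  not the p-value, does most of the filtering.
* Curated-table matching only: no sequence-based target prediction, so the
  analysis inherits the databases' coverage bias.
* The log-rank screen is univariate; no adjustment for stage mixture,
  age or treatment. "Pan-stage" means four separate significances, not one
  pooled model.
* Correlation is Pearson on log2 values; strongly non-linear repression
  would be better served by Spearman, which the configuration deliberately
  does not offer to keep the reproduced method fixed.
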