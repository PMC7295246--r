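# ceRNAstage

Stage-resolved competing endogenous RNA (ceRNA) network analysis for staged
tumour cohorts.

Under the ceRNA hypothesis, lncRNAs and mRNAs compete for shared miRNAs, so
a miRNA and the targets it represses show *negative* expression correlation.
`ceRNAstage` builds one lncRNA–miRNA–mRNA network per tumour stage (I–IV
versus normal), compares the networks across stages, and screens the miRNAs
that organise them as survival biomarkers. It is aimed at computational
biologists who want the whole chain — filtering, network assembly,
partitioning, enrichment, survival — as tested, scriptable functions rather
than a one-off analysis.

The pipeline, per stage *s*:

1. **Differential expression** vs normal: gene passes iff
   `|log2FC| ≥ 1` and Welch-t `p < 0.05`, with
   `log2FC = mean(log2(x+1))_s − mean(log2(x+1))_normal`.
2. **Target matching**: DE miRNAs × DE lncRNA/mRNA targets restricted to a
   curated interaction table.
3. **Negative-correlation filter**: keep pairs with Pearson `r < −0.1`
   (log2 scale, tumour samples of stage *s*) → a *doubly bipartite* network
   (only miRNA–lncRNA and miRNA–mRNA edges).
4. **Partition**: miRNAs in all four networks induce the common network
   (**CCEN**); miRNAs in exactly one induce that stage's unique network
   (**UCEN**); miRNAs in 2–3 stages are "shared" and belong to neither.
5. **Enrichment**: hypergeometric upper tail
   `p = Σ_{i≥k} C(M,i)C(N−M,n−i)/C(N,n)` over GMT gene sets, plus the
   enrichment efficiency `η = −log10(p)/n` for comparing lists of different
   sizes.
6. **Survival screen**: median expression split per miRNA × stage, unweighted
   log-rank `(Σ(O−E))²/ΣV ~ χ²(1)`; significant in every stage ⇒
   "pan-stage" biomarker, in exactly one ⇒ "stage-specific".

A seeded synthetic-data generator (`sim_config()` / `generate_dataset()`)
emulates the statistical structure the analysis assumes — planted
anti-correlated miRNA–target triples, decoy interactions, enriched gene
sets, exponential survival tied to miRNA expression — with a ground-truth
ledger, so every step has calibration and recovery tests.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated cohort (290 samples, 630 genes, 40 planted triples) and write
tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort + truth ledger
Rscript analysis/02_differential_expression.R
Rscript analysis/03_networks.R
Rscript analysis/04_partition.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_survival.R
```

Step 3 reports, per stage, how many matched candidates survive the
correlation filter and how many of the resulting edges are planted truth:

```
stage I: 62 candidates -> 51 edges (98% of edges planted)
stage II: 64 candidates -> 53 edges (94% of edges planted)
```

Step 4 partitions the four networks and checks them against the ledger —
all 20 all-stage planted miRNAs land in the CCEN and each stage's 5
single-stage miRNAs land in their UCEN:

```
  CCEN: 20 common miRNAs, 62 nodes, 47 edges
  UCEN-I: 5 unique miRNAs, 15 nodes, 10 edges
all-stage planted miRNAs recovered in CCEN: 20 / 20
```

Step 5 compares enrichment efficiency across the mRNA compartments over the
planted terms (higher = more annotation signal per gene):

```
  CCEN  CeRNA   UCEN
0.6978 0.6495 0.3910
```

Step 6 screens miRNAs for prognostic value; planted all-stage hazards
classify as pan-stage and single-stage hazards as stage-specific (power
permitting at 60 subjects/stage):

```
  mir_0063 (planted scope all) -> pan-stage
  mir_0080 (planted scope I) -> stage-specific:I
```

Equivalently in one call: `run_pipeline(generate_dataset(sim_config()),
out_dir = "results/run")` executes steps 2–6 and writes every table plus a
JSON manifest of counts and thresholds.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the synthetic cohort from the given seed, runs the full
pipeline end-to-end (differential expression → networks → partition →
enrichment → survival screen), logs the per-stage edge and compartment
counts, and writes the JSON report to `--out`.

The statistical guarantees live in `tests/testthat/test-acceptance.R`:
exhaustive hypergeometric-enumeration agreement, Kaplan–Meier and log-rank
oracle agreement and null calibration, DE-filter calibration, planted-edge
recovery with decoy rejection, partition invariants over fuzzed runs, and
survival-screen recovery at the stated simulation scales.
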