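#!/usr/bin/env Rscript
# Step 1 — simulate a stage-resolved ceRNA cohort.
#
# Generates the synthetic stand-in for a staged tumour expression study:
# lncRNA/miRNA/mRNA matrices over normal + stage I-IV samples, a curated-style
# miRNA-target interaction table, gene-set annotations, right-censored
# survival, and the ground-truth ledger of what was planted. Writes the
# fixture consumed by every later step.

suppressPackageStartupMessages(library(ceRNAstage))

config <- sim_config(seed = 20260917L)
dataset <- generate_dataset(config)
print(dataset)

write_fixture(dataset, "results/fixture")
cat("planted triples by scope:\n")
print(table(dataset$truth$triples$scope))
cat("prognostic miRNAs:\n")
print(dataset$truth$prognostic)
cat("fixture written to results/fixture\n")
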