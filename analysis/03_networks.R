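#!/usr/bin/env Rscript
# Step 3 — per-stage ceRNA network construction.
#
# Matches DE miRNAs to DE lncRNA/mRNA targets through the interaction table
# and keeps only pairs whose Pearson correlation (log2 scale, tumour samples
# of the stage) is strictly below -0.1. Each resulting network is doubly
# bipartite: miRNA-lncRNA and miRNA-mRNA edges only.

suppressPackageStartupMessages(library(ceRNAstage))

dataset <- read_fixture("results/fixture")
dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)

planted <- paste(dataset$truth$planted_pairs$mirna_id,
                 dataset$truth$planted_pairs$target_id)

for (s in tumor_stages()) {
  det <- differential_all_classes(dataset$expression, dataset$samples, s)
  cand <- match_targets(det, dataset$interactions)
  net <- suppressWarnings(
    build_stage_network(cand, dataset$expression, dataset$samples, s))
  stopifnot(validate_doubly_bipartite(net)$pass)
  e <- net$edges
  utils::write.table(cbind(stage = s, e),
                     sprintf("results/networks/network_stage_%s.tsv", s),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hit <- mean(paste(e$mirna_id, e$target_id) %in% planted)
  cat(sprintf("stage %s: %d candidates -> %d edges (%.0f%% of edges planted)\n",
              s, nrow(cand), nrow(e), 100 * hit))
}
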