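#!/usr/bin/env Rscript
# Step 2 — differential expression per stage versus normal.
#
# Applies the dual filter (|log2FC| >= 1, Welch p < 0.05) to each RNA class
# for each tumour stage and reports the up/down counts — the table a volcano
# plot would be drawn from.

suppressPackageStartupMessages(library(ceRNAstage))

dataset <- read_fixture("results/fixture")
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

for (s in tumor_stages()) {
  det <- differential_all_classes(dataset$expression, dataset$samples, s)
  utils::write.table(det, sprintf("results/de/de_stage_%s.tsv", s),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- table(det$class[det$is_de], det$direction[det$is_de])
  cat(sprintf("stage %s: %d DE genes\n", s, sum(det$is_de)))
  print(counts)
}
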