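test_that("identical config and seed give identical datasets", {
  a <- generate_dataset(tiny_config(seed = 11))
  b <- generate_dataset(tiny_config(seed = 11))
  expect_identical(a$expression, b$expression)
  expect_identical(a$samples, b$samples)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(tiny_config(seed = 12))
  expect_false(identical(a$expression$miRNA, c$expression$miRNA))
})

test_that("dimensions, ids and truth-ledger consistency", {
  cfg <- tiny_config(seed = 2)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$expression$lncRNA), c(cfg$n_lncRNA, 95L))
  expect_equal(dim(ds$expression$miRNA), c(cfg$n_miRNA, 95L))
  expect_equal(dim(ds$expression$mRNA), c(cfg$n_mRNA, 95L))
  expect_true(all(ds$expression$mRNA >= 0))
  expect_equal(nrow(ds$samples), 95L)
  # every planted pair appears in the interaction table
  key_int <- paste(ds$interactions$mirna_id, ds$interactions$target_id)
  key_pl <- paste(ds$truth$planted_pairs$mirna_id, ds$truth$planted_pairs$target_id)
  expect_true(all(key_pl %in% key_int))
  # planted ids exist in the matrices
  expect_true(all(ds$truth$triples$miRNA %in% rownames(ds$expression$miRNA)))
  expect_true(all(ds$truth$triples$lncRNA %in% rownames(ds$expression$lncRNA)))
  expect_true(all(ds$truth$triples$mRNA %in% rownames(ds$expression$mRNA)))
  # interaction table has no duplicate pairs
  expect_false(anyDuplicated(key_int) > 0)
})

test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(planted_correlation = 0.3), "planted_correlation")
  expect_error(sim_config(n_lncRNA = 0), "n_lncRNA")
  expect_error(sim_config(n_planted_triples = 500, n_miRNA = 10),
               "exceeds")
  expect_error(sim_config(n_samples_per_stage = c(normal = 5, I = 5)),
               "n_samples_per_stage")
})

test_that("planted pairs hit the configured anti-correlation on average", {
  # Monte-Carlo against the generator's own target: planted_correlation -0.8,
  # 60 tumour samples per stage, averaged over replicates
  rs <- c()
  for (seed in 1:15) {
    ds <- generate_dataset(tiny_config(
      seed = seed, planted_correlation = -0.8,
      n_samples_per_stage = c(normal = 10L, I = 60L, II = 10L, III = 10L,
                              IV = 10L),
      n_planted_triples = 6L, all_stage_fraction = 1))
    stage_ids <- ds$samples$sample_id[ds$samples$group == "I"]
    lm <- lapply(ds$expression, function(m) log2(m[, stage_ids] + 1))
    for (i in seq_len(nrow(ds$truth$triples))) {
      tr <- ds$truth$triples[i, ]
      rs <- c(rs,
              cor(lm$miRNA[tr$miRNA, ], lm$lncRNA[tr$lncRNA, ]),
              cor(lm$miRNA[tr$miRNA, ], lm$mRNA[tr$mRNA, ]))
    }
  }
  expect_lt(abs(mean(rs) - (-0.8)), 0.1)
})

test_that("planted differential expression hits the configured log2 fold change", {
  ds <- generate_dataset(tiny_config(
    seed = 5, planted_log2fc = 2, all_stage_fraction = 1,
    n_samples_per_stage = c(normal = 200L, I = 200L, II = 5L, III = 5L,
                            IV = 5L)))
  lm <- log2(ds$expression$miRNA + 1)
  case <- ds$samples$sample_id[ds$samples$group == "I"]
  ctrl <- ds$samples$sample_id[ds$samples$group == "normal"]
  lfc <- rowMeans(lm[ds$truth$triples$miRNA, case, drop = FALSE]) -
    rowMeans(lm[ds$truth$triples$miRNA, ctrl, drop = FALSE])
  expect_lt(max(abs(lfc - 2)), 0.5)
  expect_lt(abs(mean(lfc) - 2), 0.15)
})

test_that("null world has no correlation structure in the interaction table", {
  ds <- generate_dataset(tiny_config(seed = 3, n_planted_triples = 0,
                                     hazard_coefficient = 0,
                                     db_decoy_pairs = 40L))
  expect_equal(nrow(ds$truth$planted_pairs), 0L)
  tumor <- ds$samples$sample_id[ds$samples$group != "normal"]
  rs <- vapply(seq_len(nrow(ds$interactions)), function(i) {
    mi <- ds$interactions$mirna_id[i]
    ti <- ds$interactions$target_id[i]
    tm <- ds$expression[[ds$interactions$target_class[i]]]
    cor(log2(ds$expression$miRNA[mi, tumor] + 1), log2(tm[ti, tumor] + 1))
  }, numeric(1))
  # 80 tumour samples: null |r| should concentrate near 0
  expect_lt(abs(mean(rs)), 0.1)
  expect_lt(quantile(abs(rs), 0.9), 0.25)
})

test_that("censoring fraction tracks the configured rate under the null", {
  ds <- generate_dataset(tiny_config(
    seed = 8, n_planted_triples = 0, hazard_coefficient = 0,
    censoring_rate = 0.4,
    n_samples_per_stage = c(normal = 50L, I = 200L, II = 200L, III = 50L,
                            IV = 50L)))
  expect_lt(abs(mean(1 - ds$samples$event) - 0.4), 0.08)
  ds0 <- generate_dataset(tiny_config(seed = 8, censoring_rate = 0))
  expect_true(all(ds0$samples$event == 1L))
})

test_that("fixture round-trip reproduces the dataset exactly", {
  ds <- generate_dataset(tiny_config(seed = 4))
  dir <- withr::local_tempdir()
  write_fixture(ds, dir)
  back <- read_fixture(dir)
  expect_identical(back$expression, ds$expression)
  expect_identical(back$samples$sample_id, ds$samples$sample_id)
  expect_identical(back$samples$time, ds$samples$time)
  expect_identical(back$samples$event, ds$samples$event)
  expect_identical(back$interactions, ds$interactions)
  expect_identical(back$annotation$genes, ds$annotation$genes)
  expect_identical(back$truth$triples, ds$truth$triples)
  expect_identical(back$truth$de_genes, as.list(ds$truth$de_genes))
})

test_that("fixture files have the configured shape", {
  ds <- generate_dataset(tiny_config(
    seed = 6, n_lncRNA = 10L, n_miRNA = 10L, n_mRNA = 10L,
    n_samples_per_stage = c(normal = 2L, I = 2L, II = 2L, III = 1L, IV = 1L),
    n_planted_triples = 2L, db_decoy_pairs = 5L))
  dir <- withr::local_tempdir()
  write_fixture(ds, dir)
  lines <- readLines(file.path(dir, "expression_mRNA.tsv"))
  expect_length(lines, 11L)                                  # header + 10 genes
  expect_length(strsplit(lines[1], "\t")[[1]], 9L)           # gene_id + 8 samples
})

test_that("an empty annotation catalogue writes a valid empty GMT", {
  ann <- annotation_table(character(0), character(0), list())
  dir <- withr::local_tempdir()
  path <- file.path(dir, "empty.gmt")
  write_gmt(ann, path)
  expect_true(file.exists(path))
  back <- read_gmt(path)
  expect_length(back$term_id, 0L)
})
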