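de_row <- function(id, cls, lfc, p) {
  is_de <- abs(lfc) >= 1 & p < 0.05
  data.frame(gene_id = id, class = cls, log2fc = lfc, p_value = p,
             direction = ifelse(!is_de, "none", ifelse(lfc > 0, "up", "down")),
             is_de = is_de, degenerate = FALSE, stringsAsFactors = FALSE)
}

test_that("target matching keeps exactly the DE-DE database pairs", {
  det <- rbind(de_row("m1", "miRNA", 2, 0.001),
               de_row("m2", "miRNA", 0.2, 0.5),     # not DE
               de_row("t1", "mRNA", -1.5, 0.01),
               de_row("t2", "mRNA", -0.1, 0.9),     # not DE
               de_row("l1", "lncRNA", -2, 0.001))
  db <- data.frame(
    mirna_id = c("m1", "m1", "m2", "m1"),
    target_id = c("t1", "t2", "t1", "l1"),
    target_class = c("mRNA", "mRNA", "mRNA", "lncRNA"),
    source = "db", stringsAsFactors = FALSE)
  cand <- match_targets(det, db)
  expect_equal(sort(paste(cand$mirna_id, cand$target_id)),
               c("m1 l1", "m1 t1"))
  expect_equal(cand$mirna_direction, c("up", "up"))
  expect_equal(cand$target_direction, c("down", "down"))
  # a DE-DE pair absent from the database can never be a candidate
  expect_false("m1 t9" %in% paste(cand$mirna_id, cand$target_id))
})

test_that("class-inconsistent interaction rows are skipped with a warning", {
  det <- rbind(de_row("m1", "miRNA", 2, 0.001),
               de_row("t1", "mRNA", -1.5, 0.01))
  db <- data.frame(mirna_id = "m1", target_id = "t1",
                   target_class = "lncRNA",  # wrong class for t1
                   source = "db", stringsAsFactors = FALSE)
  expect_warning(cand <- match_targets(det, db), "inconsistent")
  expect_equal(nrow(cand), 0L)
})

test_that("pairwise correlation: exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pairwise_correlation(x, -x), -1)
  expect_equal(pairwise_correlation(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_true(is.na(pairwise_correlation(rep(2, 5), x)))
  set.seed(1)
  r <- replicate(50, pairwise_correlation(rnorm(100), rnorm(100)))
  expect_lt(mean(abs(r) < 0.2), 1.01)          # sanity
  expect_gt(mean(abs(r) < 0.2), 0.9)           # null concentration at n = 100
})

make_net_fixture <- function(r_values) {
  # three candidate pairs with controlled correlations in stage I
  n <- 30
  ids <- paste0("s", 1:n)
  samples <- data.frame(sample_id = ids, group = "I", stringsAsFactors = FALSE)
  set.seed(7)
  base <- rnorm(n)
  mk_target <- function(rho) {
    if (rho == 0) {
      # orthogonalise so the sample correlation is exactly zero
      e <- rnorm(n)
      unname(resid(lm(e ~ base))) + 6
    } else {
      sign(rho) * (abs(rho) * scale(base)[, 1] +
                     sqrt(1 - rho^2) * rnorm(n)) + 6
    }
  }
  mir <- matrix(2^(base + 6) - 1, 1, dimnames = list("m1", ids))
  tg <- t(vapply(r_values, function(r) 2^(mk_target(r) + 6) - 1, numeric(n)))
  rownames(tg) <- paste0("t", seq_along(r_values)); colnames(tg) <- ids
  cand <- data.frame(mirna_id = "m1", target_id = rownames(tg),
                     target_class = "mRNA", source = "db",
                     mirna_direction = "up", target_direction = "down",
                     stringsAsFactors = FALSE)
  list(cand = cand,
       expression = list(lncRNA = matrix(0, 0, n, dimnames = list(NULL, ids)),
                         miRNA = mir, mRNA = pmax(tg, 0)),
       samples = samples)
}

test_that("only strictly negative correlations below the threshold survive", {
  fx <- make_net_fixture(c(-0.9, 0, 0.8))
  net <- build_stage_network(fx$cand, fx$expression, fx$samples, "I",
                             network_config(correlation_threshold = -0.1))
  expect_true("t1" %in% net$edges$target_id)     # r ~ -0.9 kept
  expect_false("t2" %in% net$edges$target_id)    # r ~ 0 dropped
  expect_false("t3" %in% net$edges$target_id)    # positive dropped
  expect_true(all(net$edges$pearson_r < -0.1))
  expect_true(validate_doubly_bipartite(net)$pass)
})

test_that("a more negative threshold never adds edges", {
  ds <- generate_dataset(tiny_config(seed = 31))
  det <- differential_all_classes(ds$expression, ds$samples, "II")
  cand <- match_targets(det, ds$interactions)
  prev <- NULL
  for (thr in c(-0.05, -0.1, -0.3, -0.6, -0.9)) {
    net <- suppressWarnings(build_stage_network(
      cand, ds$expression, ds$samples, "II",
      network_config(correlation_threshold = thr)))
    cur <- paste(net$edges$mirna_id, net$edges$target_id)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("edge set equals the brute-force triple loop", {
  ds <- generate_dataset(tiny_config(seed = 32))
  for (stage in c("I", "III")) {
    det <- differential_all_classes(ds$expression, ds$samples, stage)
    cand <- match_targets(det, ds$interactions)
    net <- suppressWarnings(build_stage_network(
      cand, ds$expression, ds$samples, stage, network_config()))
    # oracle: loop over every DB pair, re-check DE and correlation directly
    de_set <- det$gene_id[det$is_de]
    sids <- ds$samples$sample_id[ds$samples$group == stage]
    expected <- character(0)
    for (i in seq_len(nrow(ds$interactions))) {
      mi <- ds$interactions$mirna_id[i]; ti <- ds$interactions$target_id[i]
      if (!(mi %in% de_set) || !(ti %in% de_set)) next
      tm <- ds$expression[[ds$interactions$target_class[i]]]
      r <- cor(log2(ds$expression$miRNA[mi, sids] + 1),
               log2(tm[ti, sids] + 1))
      if (!is.na(r) && r < -0.1) expected <- c(expected, paste(mi, ti))
    }
    expect_setequal(paste(net$edges$mirna_id, net$edges$target_id), expected)
  }
})

test_that("empty candidate list yields an empty valid network", {
  fx <- make_net_fixture(-0.9)
  net <- build_stage_network(fx$cand[0, ], fx$expression, fx$samples, "I")
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(net$nodes), 0L)
  expect_true(validate_doubly_bipartite(net)$pass)
})

test_that("validation catches forbidden structures", {
  # lncRNA-mRNA edge smuggled in via an explicit node table
  bad <- cerna_network("I",
    data.frame(mirna_id = "l1", target_id = "t1", target_class = "mRNA",
               pearson_r = -0.5, stringsAsFactors = FALSE),
    nodes = data.frame(id = c("l1", "t1"), class = c("lncRNA", "mRNA"),
                       stringsAsFactors = FALSE))
  rep_bad <- validate_doubly_bipartite(bad)
  expect_false(rep_bad$pass)
  expect_match(rep_bad$failures, "not a miRNA", all = FALSE)

  # miRNA-miRNA edge via target_class
  bad2 <- toy_network("I", "m1", "m2", "miRNA")
  expect_false(validate_doubly_bipartite(bad2)$pass)

  # a node in both roles
  bad3 <- toy_network("I", c("m1", "m2"), c("x", "m1"), c("mRNA", "mRNA"))
  rep3 <- validate_doubly_bipartite(bad3)
  expect_false(rep3$pass)
  expect_match(rep3$failures, "both as miRNA and as target", all = FALSE)

  # isolated non-miRNA node
  bad4 <- cerna_network("I",
    data.frame(mirna_id = "m1", target_id = "t1", target_class = "mRNA",
               pearson_r = -0.3, stringsAsFactors = FALSE),
    nodes = data.frame(id = c("m1", "t1", "orphan"),
                       class = c("miRNA", "mRNA", "mRNA"),
                       stringsAsFactors = FALSE))
  expect_match(validate_doubly_bipartite(bad4)$failures, "degree 0",
               all = FALSE)

  expect_true(validate_doubly_bipartite(
    cerna_network("I", data.frame(mirna_id = character(0),
                                  target_id = character(0),
                                  target_class = character(0),
                                  pearson_r = numeric(0))))$pass)
})
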