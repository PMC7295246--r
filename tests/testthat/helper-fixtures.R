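# small, fast configurations used across the unit tests

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_lncRNA = 30L, n_miRNA = 20L, n_mRNA = 60L,
    n_samples_per_stage = c(normal = 15L, I = 20L, II = 20L,
                            III = 20L, IV = 20L),
    n_planted_triples = 8L, db_decoy_pairs = 50L,
    n_terms = 10L, term_size = 12L, seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# hand-built toy network: edges given as a data frame shortcut
toy_network <- function(stage, mirnas, targets, classes, r = NULL) {
  if (is.null(r)) r <- rep(-0.5, length(mirnas))
  cerna_network(stage, data.frame(
    mirna_id = mirnas, target_id = targets, target_class = classes,
    pearson_r = r, stringsAsFactors = FALSE))
}

# brute-force Welch t-test from the textbook formulas (oracle)
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# direct hypergeometric upper tail by PMF enumeration (oracle)
hyper_oracle <- function(N, M, n, k) {
  i <- k:min(M, n)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}
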