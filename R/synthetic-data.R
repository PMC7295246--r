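#' Simulation configuration for synthetic ceRNA datasets
#'
#' Describes the "world" the generator emulates: per-class gene counts, sample
#' counts per clinical group, planted lncRNA-miRNA-mRNA triples with
#' anti-correlated expression, the composition of the interaction table, the
#' annotation catalogue, and an exponential survival model whose log-hazard
#' depends on selected miRNAs.
#'
#' Expression is log-normal on the log2 scale: a value is
#' `2^(mu_class + effect + N(0, noise_sd)) - 1`, clipped at zero, so that the
#' pipeline's `log2(x + 1)` transform recovers the latent log2 values almost
#' exactly. Planted triples place a `planted_log2fc` up-shift on the miRNA and
#' a matching down-shift on its lncRNA and mRNA targets in the tumour samples
#' of the stages they are active in; the targets additionally track the
#' miRNA's noise with a negative slope calibrated so the population Pearson
#' correlation equals `planted_correlation`.
#'
#' Triples are either active in all four stages (a fraction
#' `all_stage_fraction` of them) or in exactly one stage, cycling through
#' stages I-IV; single-stage triples are what makes the unique-network (UCEN)
#' compartment recoverable.
#'
#' @param n_lncRNA,n_miRNA,n_mRNA number of genes per RNA class.
#' @param n_samples_per_stage named integer vector with entries `normal`,
#'   `I`, `II`, `III`, `IV`.
#' @param n_planted_triples number of planted (lncRNA, miRNA, mRNA) triples.
#' @param all_stage_fraction fraction of planted triples active in all four
#'   stages; the rest are active in exactly one stage.
#' @param planted_log2fc effect size, on the log2 scale, of planted
#'   differential expression (miRNA up, targets down).
#' @param planted_correlation target population Pearson correlation between a
#'   planted miRNA and each of its targets, in `[-1, 0)`.
#' @param noise_sd standard deviation of the Gaussian noise on the log2 scale.
#' @param db_decoy_pairs number of decoy rows in the interaction table; decoys
#'   are random miRNA-target pairs with no correlation structure. If `NULL`,
#'   derived from `db_true_fraction`.
#' @param db_true_fraction fraction of the interaction table made up of
#'   planted pairs; only used when `db_decoy_pairs` is `NULL`.
#' @param n_terms,term_size annotation catalogue: number of terms and genes
#'   per term. The first `n_enriched_terms` terms are packed with planted
#'   target mRNAs so that enrichment of the planted sets is recoverable.
#' @param n_enriched_terms number of terms enriched for planted target mRNAs.
#' @param n_prognostic_all number of all-stage planted miRNAs given a
#'   survival effect in every stage.
#' @param n_prognostic_stage number of single-stage planted miRNAs per stage
#'   given a survival effect in their stage only.
#' @param hazard_coefficient log-hazard increment per standard deviation of
#'   prognostic miRNA expression (standardised within the affected samples).
#' @param base_hazard baseline exponential hazard per day. The default
#'   corresponds to a median survival of roughly 1400 days, a realistic
#'   order of magnitude for a mixed-stage lung adenocarcinoma cohort.
#' @param censoring_rate target fraction of censored subjects under the
#'   baseline hazard; censoring times are independent uniform.
#' @param seed integer seed; identical configurations (including the seed)
#'   produce byte-identical datasets.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lncRNA = 150L,
                       n_miRNA = 80L,
                       n_mRNA = 400L,
                       n_samples_per_stage = c(normal = 50L, I = 60L, II = 60L,
                                               III = 60L, IV = 60L),
                       n_planted_triples = 40L,
                       all_stage_fraction = 0.5,
                       planted_log2fc = 2,
                       planted_correlation = -0.6,
                       noise_sd = 1,
                       db_decoy_pairs = 400L,
                       db_true_fraction = NULL,
                       n_terms = 20L,
                       term_size = 25L,
                       n_enriched_terms = 3L,
                       n_prognostic_all = 2L,
                       n_prognostic_stage = 1L,
                       hazard_coefficient = 0.8,
                       base_hazard = 5e-4,
                       censoring_rate = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_lncRNA = as.integer(n_lncRNA), n_miRNA = as.integer(n_miRNA),
    n_mRNA = as.integer(n_mRNA),
    n_samples_per_stage = n_samples_per_stage,
    n_planted_triples = as.integer(n_planted_triples),
    all_stage_fraction = all_stage_fraction,
    planted_log2fc = planted_log2fc,
    planted_correlation = planted_correlation,
    noise_sd = noise_sd,
    db_decoy_pairs = if (is.null(db_decoy_pairs)) NULL else as.integer(db_decoy_pairs),
    db_true_fraction = db_true_fraction,
    n_terms = as.integer(n_terms), term_size = as.integer(term_size),
    n_enriched_terms = as.integer(n_enriched_terms),
    n_prognostic_all = as.integer(n_prognostic_all),
    n_prognostic_stage = as.integer(n_prognostic_stage),
    hazard_coefficient = hazard_coefficient,
    base_hazard = base_hazard,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_lncRNA >= 1L, cfg$n_miRNA >= 1L, cfg$n_mRNA >= 1L,
    cfg$n_planted_triples >= 0L,
    cfg$all_stage_fraction >= 0, cfg$all_stage_fraction <= 1,
    cfg$noise_sd > 0,
    cfg$n_terms >= 0L, cfg$term_size >= 1L,
    cfg$censoring_rate >= 0, cfg$censoring_rate < 1,
    cfg$base_hazard > 0,
    length(cfg$seed) == 1L, !is.na(cfg$seed)
  )
  if (cfg$planted_correlation >= 0 || cfg$planted_correlation < -1)
    stop("planted_correlation must lie in [-1, 0)")
  groups <- c("normal", "I", "II", "III", "IV")
  if (!all(groups %in% names(cfg$n_samples_per_stage)))
    stop("n_samples_per_stage must name groups: ", paste(groups, collapse = ", "))
  if (any(cfg$n_samples_per_stage < 1))
    stop("each group needs at least one sample")
  if (cfg$n_planted_triples > min(cfg$n_lncRNA, cfg$n_miRNA, cfg$n_mRNA))
    stop("n_planted_triples exceeds the smallest gene-class count")
  invisible(cfg)
}

#' The clinical stage labels used throughout
#' @return character vector `c("I", "II", "III", "IV")`.
#' @export
tumor_stages <- function() c("I", "II", "III", "IV")

#' Generate a synthetic stage-resolved ceRNA dataset
#'
#' Draws per-class expression matrices (linear scale, genes x samples), a
#' sample table with clinical group and right-censored survival, a
#' miRNA-target interaction table containing every planted pair plus decoys,
#' a gene-set annotation catalogue, and a ground-truth ledger recording what
#' was planted (for recovery tests).
#'
#' Survival follows an exponential model: for each tumour sample the hazard is
#' `base_hazard * exp(hazard_coefficient * sum(z))`, summing the standardised
#' expression `z` of every prognostic miRNA whose scope covers the sample's
#' stage. Censoring times are uniform on `(0, b)` with `b` solved so the
#' expected censoring fraction under the baseline hazard equals
#' `censoring_rate`.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `cerna_dataset` with elements `expression` (list of
#'   matrices `lncRNA`, `miRNA`, `mRNA`), `samples` (data frame: sample_id,
#'   group, time, event), `interactions` (data frame: mirna_id, target_id,
#'   target_class, source), `annotation` (an `annotation_table`), and `truth`
#'   (the planted-truth ledger).
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  stages <- tumor_stages()
  groups <- c("normal", stages)

  ## ---- samples -------------------------------------------------------------
  n_per <- config$n_samples_per_stage[groups]
  group <- rep(groups, times = n_per)
  n_samples <- length(group)
  sample_id <- sprintf("sample_%04d", seq_len(n_samples))

  ## ---- gene ids and baselines ---------------------------------------------
  ids <- list(
    lncRNA = sprintf("lnc_%04d", seq_len(config$n_lncRNA)),
    miRNA  = sprintf("mir_%04d", seq_len(config$n_miRNA)),
    mRNA   = sprintf("mrna_%04d", seq_len(config$n_mRNA))
  )
  # class baselines on the log2 scale; high enough that 2^x - 1 rarely clips
  mu <- c(lncRNA = 4, miRNA = 6, mRNA = 8)

  log2mat <- lapply(names(ids), function(cl) {
    m <- matrix(stats::rnorm(length(ids[[cl]]) * n_samples, mu[[cl]], config$noise_sd),
                nrow = length(ids[[cl]]), ncol = n_samples,
                dimnames = list(ids[[cl]], sample_id))
    m
  })
  names(log2mat) <- names(ids)

  ## ---- planted triples -----------------------------------------------------
  nt <- config$n_planted_triples
  triples <- data.frame(lncRNA = character(0), miRNA = character(0),
                        mRNA = character(0), scope = character(0),
                        stringsAsFactors = FALSE)
  if (nt > 0L) {
    n_all <- round(config$all_stage_fraction * nt)
    scope <- c(rep("all", n_all),
               rep(stages, length.out = nt - n_all))
    triples <- data.frame(
      lncRNA = sample(ids$lncRNA, nt),
      miRNA  = sample(ids$miRNA, nt),
      mRNA   = sample(ids$mRNA, nt),
      scope  = scope,
      stringsAsFactors = FALSE
    )
  }

  # slope 1 on the miRNA's noise; target noise sd chosen so that the
  # population correlation equals planted_correlation
  rho <- abs(config$planted_correlation)
  sd_t <- config$noise_sd * sqrt(1 / rho^2 - 1)

  for (i in seq_len(nrow(triples))) {
    tr <- triples[i, ]
    active_stages <- if (tr$scope == "all") stages else tr$scope
    cols <- which(group %in% active_stages)
    e_m <- stats::rnorm(length(cols), 0, config$noise_sd)
    log2mat$miRNA[tr$miRNA, cols] <- mu[["miRNA"]] + config$planted_log2fc + e_m
    for (tgt in c("lncRNA", "mRNA")) {
      e_t <- stats::rnorm(length(cols), 0, sd_t)
      log2mat[[tgt]][tr[[tgt]], cols] <-
        mu[[tgt]] - config$planted_log2fc - e_m + e_t
    }
  }

  ## ---- interaction table ---------------------------------------------------
  planted_pairs <- if (nt > 0L) {
    rbind(
      data.frame(mirna_id = triples$miRNA, target_id = triples$lncRNA,
                 target_class = "lncRNA", stringsAsFactors = FALSE),
      data.frame(mirna_id = triples$miRNA, target_id = triples$mRNA,
                 target_class = "mRNA", stringsAsFactors = FALSE)
    )
  } else {
    data.frame(mirna_id = character(0), target_id = character(0),
               target_class = character(0), stringsAsFactors = FALSE)
  }

  n_decoy <- config$db_decoy_pairs
  if (is.null(n_decoy)) {
    if (is.null(config$db_true_fraction) || config$db_true_fraction <= 0)
      stop("supply db_decoy_pairs or a positive db_true_fraction")
    n_decoy <- as.integer(round(nrow(planted_pairs) *
                                  (1 / config$db_true_fraction - 1)))
  }
  decoys <- draw_decoy_pairs(n_decoy, ids, planted_pairs)
  interactions <- rbind(
    cbind(planted_pairs, source = rep("synthdb", nrow(planted_pairs))),
    cbind(decoys, source = rep("synthdb", nrow(decoys)))
  )
  rownames(interactions) <- NULL

  ## ---- annotation catalogue ------------------------------------------------
  n_enr <- min(config$n_enriched_terms, config$n_terms,
               if (nt > 0L) config$n_terms else 0L)
  term_ids <- sprintf("TERM_%03d", seq_len(config$n_terms))
  planted_targets <- unique(triples$mRNA)
  term_genes <- lapply(seq_len(config$n_terms), function(j) {
    size <- min(config$term_size, config$n_mRNA)
    if (j <= n_enr && length(planted_targets) > 0L) {
      core <- sample(planted_targets, min(length(planted_targets), size))
      fill <- setdiff(ids$mRNA, core)
      c(core, sample(fill, size - length(core)))
    } else {
      sample(ids$mRNA, size)
    }
  })
  annotation <- annotation_table(
    term_id = term_ids,
    term_name = sprintf("synthetic process %03d", seq_len(config$n_terms)),
    genes = term_genes
  )

  ## ---- prognostic miRNAs and survival -------------------------------------
  all_scope_mirs <- triples$miRNA[triples$scope == "all"]
  prognostic <- data.frame(mirna_id = character(0), scope = character(0),
                           stringsAsFactors = FALSE)
  if (config$n_prognostic_all > 0L && length(all_scope_mirs) > 0L) {
    prognostic <- rbind(prognostic, data.frame(
      mirna_id = all_scope_mirs[seq_len(min(config$n_prognostic_all,
                                            length(all_scope_mirs)))],
      scope = "all", stringsAsFactors = FALSE))
  }
  if (config$n_prognostic_stage > 0L) {
    for (s in stages) {
      pool <- triples$miRNA[triples$scope == s]
      if (length(pool) > 0L) {
        prognostic <- rbind(prognostic, data.frame(
          mirna_id = pool[seq_len(min(config$n_prognostic_stage, length(pool)))],
          scope = s, stringsAsFactors = FALSE))
      }
    }
  }

  lp <- numeric(n_samples)  # log-hazard linear predictor; zero for normals
  if (config$hazard_coefficient != 0 && nrow(prognostic) > 0L) {
    for (i in seq_len(nrow(prognostic))) {
      sc <- prognostic$scope[i]
      affected <- if (sc == "all") which(group %in% stages) else which(group == sc)
      x <- log2mat$miRNA[prognostic$mirna_id[i], affected]
      z <- as.numeric(scale(x))
      lp[affected] <- lp[affected] + config$hazard_coefficient * z
    }
  }
  rate <- config$base_hazard * exp(lp)
  t_event <- stats::rexp(n_samples, rate)
  if (config$censoring_rate > 0) {
    b <- uniform_censor_bound(config$base_hazard, config$censoring_rate)
    t_cens <- stats::runif(n_samples, 0, b)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n_samples)
  }

  samples <- data.frame(sample_id = sample_id, group = group,
                        time = time, event = event, stringsAsFactors = FALSE)

  ## ---- linear-scale expression --------------------------------------------
  expression <- lapply(log2mat, function(m) pmax(2^m - 1, 0))

  de_genes <- stats::setNames(lapply(stages, function(s) {
    keep <- triples$scope == "all" | triples$scope == s
    unique(c(triples$lncRNA[keep], triples$miRNA[keep], triples$mRNA[keep]))
  }), stages)

  truth <- list(
    triples = triples,
    planted_pairs = planted_pairs,
    de_genes = de_genes,
    enriched_terms = term_ids[seq_len(n_enr)],
    prognostic = prognostic
  )

  structure(list(expression = expression, samples = samples,
                 interactions = interactions, annotation = annotation,
                 truth = truth, config = config),
            class = "cerna_dataset")
}

# decoy miRNA-target pairs, distinct from planted pairs and from each other
draw_decoy_pairs <- function(n_decoy, ids, planted_pairs) {
  if (n_decoy <= 0L) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_class = character(0), stringsAsFactors = FALSE))
  }
  targets <- c(ids$lncRNA, ids$mRNA)
  tclass <- rep(c("lncRNA", "mRNA"), c(length(ids$lncRNA), length(ids$mRNA)))
  seen <- paste(planted_pairs$mirna_id, planted_pairs$target_id)
  out_m <- character(0); out_t <- character(0); out_c <- character(0)
  guard <- 0L
  while (length(out_m) < n_decoy && guard < 50L) {
    need <- n_decoy - length(out_m)
    mi <- sample(ids$miRNA, 2L * need, replace = TRUE)
    ti <- sample(seq_along(targets), 2L * need, replace = TRUE)
    key <- paste(mi, targets[ti])
    ok <- !(key %in% seen) & !duplicated(key)
    take <- which(ok)[seq_len(min(need, sum(ok)))]
    seen <- c(seen, key[take])
    out_m <- c(out_m, mi[take])
    out_t <- c(out_t, targets[ti][take])
    out_c <- c(out_c, tclass[ti][take])
    guard <- guard + 1L
  }
  data.frame(mirna_id = out_m, target_id = out_t, target_class = out_c,
             stringsAsFactors = FALSE)
}

# bound b of the uniform censoring distribution U(0, b) such that
# P(C < T) = (1 - exp(-lambda b)) / (lambda b) equals the target rate
uniform_censor_bound <- function(lambda, target) {
  f <- function(b) (1 - exp(-lambda * b)) / (lambda * b) - target
  # censoring fraction decreases from 1 (b -> 0) towards 0 (b -> Inf)
  upper <- 1 / lambda
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(1e-8 / lambda, upper), tol = 1e-10)$root
}

#' @export
print.cerna_dataset <- function(x, ...) {
  cat("Synthetic ceRNA dataset\n")
  cat(sprintf("  genes: %d lncRNA, %d miRNA, %d mRNA\n",
              nrow(x$expression$lncRNA), nrow(x$expression$miRNA),
              nrow(x$expression$mRNA)))
  tab <- table(x$samples$group)
  cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  interactions: %d rows (%d planted pairs)\n",
              nrow(x$interactions), nrow(x$truth$planted_pairs)))
  cat(sprintf("  annotation: %d terms; planted triples: %d\n",
              length(x$annotation$term_id), nrow(x$truth$triples)))
  invisible(x)
}
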