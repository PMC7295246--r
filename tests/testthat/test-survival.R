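test_that("Kaplan-Meier estimate: hand-checked cases", {
  # two subjects, deaths at t = 1 and t = 2
  km <- km_curve(c(1, 2), c(1, 1))
  expect_equal(km$surv, c(0.5, 0))
  # all censored: survival never drops
  km2 <- km_curve(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # one death among four, the rest censored later
  km3 <- km_curve(c(5, 6, 7, 8), c(1, 0, 0, 0))
  expect_equal(km_survival_at(km3, 5), 0.75)
  expect_equal(km_survival_at(km3, 4.9), 1)
  # deaths processed before censorings at tied times
  km4 <- km_curve(c(2, 2, 2, 4), c(1, 0, 1, 1))
  expect_equal(km4$surv[km4$time == 2], 0.5)   # 2 deaths out of 4 at risk
})

test_that("with no censoring the curve equals empirical survival fractions", {
  set.seed(10)
  t <- round(rexp(40, 0.1), 1)
  km <- km_curve(t, rep(1, 40))
  dead_times <- km$time
  emp <- vapply(dead_times, function(tt) mean(t > tt), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("Kaplan-Meier matches the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    t <- sample(1:12, n, replace = TRUE)           # plenty of ties
    e <- rbinom(n, 1, 0.6)
    if (sum(e) == 0) e[1] <- 1
    km <- km_curve(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    ref <- stats::setNames(sf$surv, sf$time)
    expect_equal(km$surv[match(sf$time, km$time)], unname(ref),
                 tolerance = 1e-12)
  }
})

test_that("log-rank statistic matches the observed-minus-expected oracle", {
  # independently coded O-E/V accumulation over pooled death times
  logrank_oracle <- function(ta, ea, tb, eb) {
    times <- c(ta, tb); events <- c(ea, eb)
    g <- rep(1:2, c(length(ta), length(tb)))
    O <- E <- V <- 0
    for (t in sort(unique(times[events == 1]))) {
      n1 <- sum(ta >= t); n2 <- sum(tb >= t); n <- n1 + n2
      d <- sum(events == 1 & times == t)
      O <- O + sum(ea == 1 & ta == t)
      E <- E + d * n1 / n
      if (n > 1) V <- V + d * n1 * n2 * (n - d) / (n^2 * (n - 1))
    }
    (O - E)^2 / V
  }
  ta <- c(3, 5, 7, 9, 11, 14); ea <- c(1, 1, 0, 1, 0, 1)
  tb <- c(2, 4, 6, 8, 10, 12); eb <- c(1, 0, 1, 1, 1, 0)
  lr <- logrank_test(ta, ea, tb, eb)
  expect_equal(lr$chi_square, logrank_oracle(ta, ea, tb, eb),
               tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(lr$chi_square, 1, lower.tail = FALSE))
  # identical groups carry no signal
  lr0 <- logrank_test(ta, ea, ta, ea)
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)
  expect_error(logrank_test(numeric(0), numeric(0), tb, eb), "non-empty")
})

test_that("log-rank agrees with survival::survdiff on random data", {
  skip_if_not_installed("survival")
  set.seed(13)
  for (i in 1:20) {
    na <- sample(5:25, 1); nb <- sample(5:25, 1)
    ta <- sample(1:15, na, replace = TRUE); ea <- rbinom(na, 1, 0.7)
    tb <- sample(1:15, nb, replace = TRUE); eb <- rbinom(nb, 1, 0.7)
    if (sum(ea) + sum(eb) == 0) ea[1] <- 1
    sd_ref <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, c(na, nb)))
    lr <- logrank_test(ta, ea, tb, eb)
    expect_equal(lr$chi_square, unname(sd_ref$chisq), tolerance = 1e-10)
  }
})

test_that("permuted labels under the null give approximately uniform p", {
  set.seed(21)
  t <- rexp(40, 0.01); e <- rbinom(40, 1, 0.7)
  ps <- replicate(200, {
    idx <- sample(40, 20)
    lr <- logrank_test(t[idx], e[idx], t[-idx], e[-idx])
    lr$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("median split sends ties to the low group", {
  clin <- data.frame(sample_id = paste0("s", 1:4), group = "I",
                     time = 1:4, event = 1, stringsAsFactors = FALSE)
  v <- setNames(c(1, 2, 3, 4), clin$sample_id)
  g <- split_by_expression(v, clin)
  expect_setequal(g$sample_id[g$expr_group == "low"], c("s1", "s2"))
  expect_setequal(g$sample_id[g$expr_group == "high"], c("s3", "s4"))
  # odd count: the median itself goes low
  clin3 <- clin[1:3, ]
  g3 <- split_by_expression(setNames(c(1, 2, 3), clin3$sample_id), clin3)
  expect_setequal(g3$sample_id[g3$expr_group == "low"], c("s1", "s2"))
  expect_equal(g3$sample_id[g3$expr_group == "high"], "s3")
  expect_error(split_by_expression(setNames(rep(2, 4), clin$sample_id), clin),
               "degenerate split")
})

test_that("survival screen recovers planted prognostic structure", {
  cfg <- tiny_config(
    seed = 61, n_planted_triples = 6L, all_stage_fraction = 0.5,
    n_samples_per_stage = c(normal = 10L, I = 120L, II = 120L, III = 120L,
                            IV = 120L),
    n_prognostic_all = 1L, n_prognostic_stage = 1L, hazard_coefficient = 1)
  ds <- generate_dataset(cfg)
  prog <- ds$truth$prognostic
  pan_mir <- prog$mirna_id[prog$scope == "all"]
  spec_mir <- prog$mirna_id[prog$scope %in% tumor_stages()][1]
  spec_stage <- prog$scope[prog$mirna_id == spec_mir]
  null_mir <- setdiff(rownames(ds$expression$miRNA),
                      c(prog$mirna_id, ds$truth$triples$miRNA))[1]
  scr <- survival_screen(c(pan_mir, spec_mir, null_mir),
                         ds$expression$miRNA, ds$samples)
  cls <- setNames(scr$classification$classification,
                  scr$classification$mirna_id)
  expect_equal(unname(cls[pan_mir]), "pan-stage")
  expect_equal(unname(cls[spec_mir]), paste0("stage-specific:", spec_stage))
  # classification is a deterministic function of the emitted p matrix
  expect_identical(classify_screen(scr$screen, 0.05), scr$classification)
  # every reported cell is reproducible from the inputs
  cell <- scr$screen[scr$screen$mirna_id == pan_mir &
                       scr$screen$stage == "II", ]
  sub <- ds$samples[ds$samples$group == "II", ]
  grp <- split_by_expression(ds$expression$miRNA[pan_mir, sub$sample_id], sub)
  lr <- logrank_test(grp$time[grp$expr_group == "low"],
                     grp$event[grp$expr_group == "low"],
                     grp$time[grp$expr_group == "high"],
                     grp$event[grp$expr_group == "high"])
  expect_equal(cell$p, lr$p_value, tolerance = 1e-12)
})

test_that("small stages are reported as not evaluable", {
  cfg <- tiny_config(
    seed = 62, n_samples_per_stage = c(normal = 10L, I = 20L, II = 20L,
                                       III = 20L, IV = 2L))
  ds <- generate_dataset(cfg)
  mir <- rownames(ds$expression$miRNA)[1]
  scr <- survival_screen(mir, ds$expression$miRNA, ds$samples)
  iv <- scr$screen[scr$screen$stage == "IV", ]
  expect_false(iv$evaluable)
  expect_true(is.na(iv$p))
  expect_error(survival_screen("not_a_mirna", ds$expression$miRNA, ds$samples),
               "absent")
})
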