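#' Kaplan-Meier product-limit survival estimate
#'
#' The survival probability is a step function updated only at death times:
#' `S(t_i) = S(t_{i-1}) * (1 - d_i / n_i)`, where `n_i` subjects are at risk
#' just before `t_i` and `d_i` die at `t_i`. Censored subjects leave the risk
#' set without a step. At tied times, deaths are processed before censorings
#' (both are counted in the risk set at that time).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = death observed, 0 = censored).
#' @return object of class `km_curve`: a data frame with one row per distinct
#'   observed time — `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) > 0L,
            all(times >= 0))
  events <- as.integer(events)
  ut <- sort(unique(times))
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- numeric(length(ut))
  at_risk <- length(times)
  s <- 1
  for (i in seq_along(ut)) {
    d <- sum(events == 1L & times == ut[i])
    c_ <- sum(events == 0L & times == ut[i])
    n_risk[i] <- at_risk
    n_event[i] <- d
    n_censor[i] <- c_
    if (d > 0L) s <- s * (1 - d / at_risk)
    surv[i] <- s
    at_risk <- at_risk - d - c_
  }
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param curve a `km_curve`.
#' @param t numeric vector of times.
#' @return survival probabilities (1 before the first observed time).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0L) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Unweighted two-group log-rank test
#'
#' The standard chi-square log-rank statistic with all time points weighted
#' equally: at each distinct death time the observed deaths in group A are
#' compared with their hypergeometric expectation given the pooled risk sets,
#' and `(sum(O - E))^2 / sum(V)` is referred to a chi-square distribution
#' with one degree of freedom.
#'
#' @param times_a,events_a follow-up times and event indicators, group A.
#' @param times_b,events_b follow-up times and event indicators, group B.
#' @return object of class `logrank_result`: `chi_square`, `df`, `p_value`,
#'   `n_a`, `n_b`, `observed` and `expected` deaths in group A.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) == length(events_a),
            length(times_b) == length(events_b))
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be non-empty")
  times <- c(times_a, times_b)
  events <- as.integer(c(events_a, events_b))
  grp <- rep(c(1L, 2L), c(length(times_a), length(times_b)))
  dt <- sort(unique(times[events == 1L]))
  O <- E <- V <- 0
  for (t in dt) {
    at_risk <- times >= t
    n1 <- sum(at_risk & grp == 1L)
    n2 <- sum(at_risk & grp == 2L)
    n <- n1 + n2
    d <- sum(events == 1L & times == t)
    d1 <- sum(events == 1L & times == t & grp == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1L) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  structure(list(chi_square = chi, df = 1L,
                 p_value = if (V > 0) stats::pchisq(chi, 1, lower.tail = FALSE) else 1,
                 n_a = length(times_a), n_b = length(times_b),
                 observed = O, expected = E),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4g on 1 df, p = %.4g (n = %d vs %d)\n",
              x$chi_square, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Split samples into high/low expression groups
#'
#' Default rule: median split with ties assigned to the low group (a sample
#' is "high" when its value is strictly above the threshold).
#'
#' @param values named numeric vector of expression values (names are sample
#'   ids).
#' @param clinical data frame with a `sample_id` column; only samples present
#'   in both are used.
#' @param rule `"median"`, `"mean"`, or `"quantile"`.
#' @param q quantile used when `rule = "quantile"`.
#' @return the matching clinical rows with an added `expr_group` column
#'   (`"low"` / `"high"`).
#' @export
split_by_expression <- function(values, clinical,
                                rule = c("median", "mean", "quantile"),
                                q = 0.5) {
  rule <- match.arg(rule)
  common <- intersect(names(values), clinical$sample_id)
  if (length(common) < 2L) stop("need at least two samples with both ",
                                "expression and clinical data")
  v <- values[common]
  if (max(v) == min(v)) stop("degenerate split: all expression values identical")
  thr <- switch(rule,
                median = stats::median(v),
                mean = mean(v),
                quantile = stats::quantile(v, q, names = FALSE))
  out <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  out$expr_group <- ifelse(v > thr, "high", "low")
  rownames(out) <- NULL
  out
}

#' Screen miRNAs for prognostic value per stage and pooled
#'
#' For every miRNA and every stage (plus the pooled tumour cohort), samples
#' are split into high/low expression groups and compared with the log-rank
#' test. A miRNA is classified "pan-stage" when its p-value is at or below
#' `alpha` in every evaluable stage, and "stage-specific:s" when significant
#' in stage s only. Stages with fewer than four subjects (or a degenerate
#' split) are reported as not evaluable and excluded from classification.
#' The full p-value matrix is the primary output; the classification at
#' `alpha` is advisory.
#'
#' @param mirna_ids miRNAs to screen (must be rows of `mirna_expression`).
#' @param mirna_expression linear-scale miRNA expression matrix.
#' @param clinical data frame: sample_id, group (stage or "normal"), time,
#'   event.
#' @param alpha significance level for the classification, default 0.05.
#' @param split_rule,split_q grouping rule passed to [split_by_expression()].
#' @return list of class `survival_screen`: `screen` (data frame mirna_id,
#'   stage, n_low, n_high, chi_square, p, evaluable) and `classification`
#'   (data frame mirna_id, classification).
#' @export
survival_screen <- function(mirna_ids, mirna_expression, clinical,
                            alpha = 0.05,
                            split_rule = c("median", "mean", "quantile"),
                            split_q = 0.5) {
  split_rule <- match.arg(split_rule)
  missing_ids <- setdiff(mirna_ids, rownames(mirna_expression))
  if (length(missing_ids)) stop("miRNA(s) absent from the expression matrix: ",
                                paste(utils::head(missing_ids, 5), collapse = ", "))
  stages <- tumor_stages()
  tumor <- clinical[clinical$group %in% stages, , drop = FALSE]

  one_cell <- function(mid, clin_sub) {
    if (nrow(clin_sub) < 4L)
      return(list(n_low = NA_integer_, n_high = NA_integer_,
                  chi = NA_real_, p = NA_real_, evaluable = FALSE))
    vals <- mirna_expression[mid, intersect(colnames(mirna_expression),
                                            clin_sub$sample_id)]
    grp <- tryCatch(split_by_expression(vals, clin_sub, rule = split_rule,
                                        q = split_q),
                    error = function(e) NULL)
    if (is.null(grp) || length(unique(grp$expr_group)) < 2L)
      return(list(n_low = NA_integer_, n_high = NA_integer_,
                  chi = NA_real_, p = NA_real_, evaluable = FALSE))
    lo <- grp[grp$expr_group == "low", ]
    hi <- grp[grp$expr_group == "high", ]
    lr <- logrank_test(lo$time, lo$event, hi$time, hi$event)
    list(n_low = nrow(lo), n_high = nrow(hi),
         chi = lr$chi_square, p = lr$p_value, evaluable = TRUE)
  }

  rows <- list()
  for (mid in mirna_ids) {
    for (sc in c(stages, "pooled")) {
      clin_sub <- if (sc == "pooled") tumor else
        tumor[tumor$group == sc, , drop = FALSE]
      cell <- one_cell(mid, clin_sub)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mid, stage = sc, n_low = cell$n_low, n_high = cell$n_high,
        chi_square = cell$chi, p = cell$p, evaluable = cell$evaluable,
        stringsAsFactors = FALSE)
    }
  }
  screen <- do.call(rbind, rows)
  classification <- classify_screen(screen, alpha)
  structure(list(screen = screen, classification = classification,
                 alpha = alpha),
            class = "survival_screen")
}

#' Classify miRNAs from a screen p-value table
#'
#' Deterministic function of the per-stage p-values and alpha: "pan-stage"
#' if p <= alpha in every evaluable stage (with at least one evaluable),
#' "stage-specific:s" if p <= alpha in exactly one evaluable stage s,
#' otherwise "none".
#'
#' @param screen the per-(miRNA, stage) table from [survival_screen()].
#' @param alpha significance level.
#' @return data frame: mirna_id, classification.
#' @export
classify_screen <- function(screen, alpha = 0.05) {
  per_stage <- screen[screen$stage %in% tumor_stages(), , drop = FALSE]
  out <- lapply(split(per_stage, per_stage$mirna_id), function(df) {
    ev <- df[df$evaluable, , drop = FALSE]
    cls <- "none"
    if (nrow(ev) > 0L) {
      sig <- ev$p <= alpha
      if (all(sig)) cls <- "pan-stage"
      else if (sum(sig) == 1L) cls <- paste0("stage-specific:", ev$stage[sig])
    }
    data.frame(mirna_id = df$mirna_id[1], classification = cls,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[match(unique(per_stage$mirna_id), res$mirna_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @export
print.survival_screen <- function(x, ...) {
  cat(sprintf("survival screen: %d miRNAs x %d stage cells (alpha = %g)\n",
              length(unique(x$screen$mirna_id)), nrow(x$screen), x$alpha))
  tab <- table(x$classification$classification)
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}
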