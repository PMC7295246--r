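#' Differential-expression filter configuration
#'
#' The dual filter used throughout: a gene is called differentially expressed
#' when its absolute log2 fold change reaches `log2fc_threshold` (inclusive)
#' AND its two-sided p-value is below `p_threshold` (strict). Defaults are the
#' conventional |log2FC| >= 1 and p < 0.05 cuts. No multiple-testing
#' correction is applied; see the methods vignette for why this is a
#' documented limitation rather than an oversight.
#'
#' @param log2fc_threshold positive real, default 1.
#' @param p_threshold p-value cut in (0, 1), default 0.05.
#' @param pseudocount added before the log2 transform, default 1.
#' @return object of class `de_config`.
#' @export
de_config <- function(log2fc_threshold = 1, p_threshold = 0.05, pseudocount = 1) {
  stopifnot(log2fc_threshold > 0, p_threshold > 0, p_threshold < 1,
            pseudocount > 0)
  structure(list(log2fc_threshold = log2fc_threshold,
                 p_threshold = p_threshold,
                 pseudocount = pseudocount),
            class = "de_config")
}

#' Log2 transform with pseudocount
#' @param mat non-negative numeric matrix (or vector).
#' @param pseudocount positive real added before taking log2.
#' @return `log2(mat + pseudocount)`, same shape.
#' @export
log_transform <- function(mat, pseudocount = 1) {
  if (any(mat < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  stopifnot(pseudocount > 0)
  log2(mat + pseudocount)
}

#' Log2 fold change between two groups of log2 values
#'
#' Difference of group means on the log2 scale (case minus control); inputs
#' must already be log2-transformed.
#'
#' @param case_values,control_values non-empty numeric vectors.
#' @return the log2 fold change (a single real).
#' @export
compute_log2fc <- function(case_values, control_values) {
  if (length(case_values) == 0L || length(control_values) == 0L)
    stop("both groups must be non-empty")
  mean(case_values) - mean(control_values)
}

#' Welch two-sample t-test on log2 expression values
#'
#' Two-sided, unequal variances. Degenerate inputs — a group with fewer than
#' two values, or both groups constant — cannot support a test; they are
#' reported as p = 1 with `degenerate = TRUE` so the gene is retained but can
#' never be called differentially expressed.
#'
#' @param case_values,control_values numeric vectors of log2 values.
#' @return list with `statistic`, `p_value`, `df`, `degenerate`.
#' @export
two_sample_test <- function(case_values, control_values) {
  degen <- length(case_values) < 2L || length(control_values) < 2L ||
    (stats::var(case_values) == 0 && stats::var(control_values) == 0)
  if (!degen) {
    # t.test() also rejects near-constant data; treat that as degenerate too
    ht <- tryCatch(stats::t.test(case_values, control_values, var.equal = FALSE),
                   error = function(e) NULL)
    if (!is.null(ht)) {
      return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                  df = unname(ht$parameter), degenerate = FALSE))
    }
  }
  list(statistic = 0, p_value = 1, df = NA_real_, degenerate = TRUE)
}

#' Differential expression of one RNA class for one stage versus normal
#'
#' For every gene, computes the log2 fold change (difference of mean log2
#' expression, tumour-stage minus normal) and a Welch t-test p-value, then
#' applies the dual filter of [de_config()]. Genes with degenerate data are
#' retained with `is_de = FALSE`, never dropped.
#'
#' @param matrix expression matrix on the linear scale (genes x samples); the
#'   log2(x + pseudocount) transform is applied internally.
#' @param sample_table data frame with `sample_id` and `group` columns.
#' @param stage one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param config a [de_config()].
#' @param rna_class optional class label recorded in the output.
#' @return data frame (one row per gene): gene_id, class, log2fc, p_value,
#'   direction in {up, down, none}, is_de, degenerate.
#' @export
differential_genes <- function(matrix, sample_table, stage,
                               config = de_config(), rna_class = NA_character_) {
  if (!stage %in% tumor_stages()) stop("unknown stage label: ", stage)
  case_ids <- sample_table$sample_id[sample_table$group == stage]
  ctrl_ids <- sample_table$sample_id[sample_table$group == "normal"]
  case_ids <- intersect(case_ids, colnames(matrix))
  ctrl_ids <- intersect(ctrl_ids, colnames(matrix))
  if (length(ctrl_ids) < 2L) stop("need at least two normal samples")
  if (length(case_ids) < 2L) stop("need at least two samples in stage ", stage)

  lm <- log_transform(matrix, config$pseudocount)
  case <- lm[, case_ids, drop = FALSE]
  ctrl <- lm[, ctrl_ids, drop = FALSE]

  lfc <- rowMeans(case) - rowMeans(ctrl)
  res <- lapply(seq_len(nrow(lm)), function(i)
    two_sample_test(case[i, ], ctrl[i, ]))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  degen <- vapply(res, `[[`, logical(1), "degenerate")

  is_de <- abs(lfc) >= config$log2fc_threshold & p < config$p_threshold
  direction <- ifelse(!is_de, "none", ifelse(lfc > 0, "up", "down"))
  data.frame(gene_id = rownames(lm), class = rna_class, log2fc = unname(lfc),
             p_value = p, direction = direction, is_de = is_de,
             degenerate = degen, stringsAsFactors = FALSE)
}

#' Differential expression for all three RNA classes at one stage
#'
#' Convenience wrapper running [differential_genes()] on each class matrix of
#' a dataset and row-binding the results.
#'
#' @param expression named list of matrices (`lncRNA`, `miRNA`, `mRNA`).
#' @param sample_table sample data frame.
#' @param stage tumour stage label.
#' @param config a [de_config()].
#' @return combined DE table covering all three classes.
#' @export
differential_all_classes <- function(expression, sample_table, stage,
                                     config = de_config()) {
  out <- lapply(names(expression), function(cl)
    differential_genes(expression[[cl]], sample_table, stage, config,
                       rna_class = cl))
  do.call(rbind, out)
}
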