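#' Network construction configuration
#'
#' @param correlation_threshold negative real; an interaction pair becomes an
#'   edge only when its Pearson correlation is strictly below this value.
#'   Default -0.1, the conventional ceRNA negative-correlation cut.
#' @param correlation_sample_scope which samples enter the correlation:
#'   tumour samples of the stage only (default) or tumour plus normal.
#' @param min_samples minimum paired samples required to correlate a pair.
#' @return object of class `network_config`.
#' @export
network_config <- function(correlation_threshold = -0.1,
                           correlation_sample_scope = c("stage_tumor",
                                                        "tumor_plus_normal"),
                           min_samples = 3L) {
  if (correlation_threshold >= 0) stop("correlation_threshold must be negative")
  stopifnot(min_samples >= 3L)
  structure(list(correlation_threshold = correlation_threshold,
                 correlation_sample_scope = match.arg(correlation_sample_scope),
                 min_samples = as.integer(min_samples)),
            class = "network_config")
}

#' ceRNA network container
#'
#' A stage-labelled tripartite (doubly bipartite) graph: nodes are lncRNAs,
#' miRNAs and mRNAs; edges connect a miRNA to a lncRNA or mRNA target and
#' carry the Pearson correlation that admitted them. Nodes are derived from
#' the edge endpoints unless an explicit node table is supplied (useful for
#' hand-building invalid networks in validation tests).
#'
#' @param stage stage label (or a compartment label such as "CCEN").
#' @param edges data frame: mirna_id, target_id, target_class, pearson_r.
#' @param nodes optional data frame (id, class) overriding the derived nodes.
#' @return object of class `cerna_network`.
#' @export
cerna_network <- function(stage, edges, nodes = NULL) {
  need <- c("mirna_id", "target_id", "target_class", "pearson_r")
  if (nrow(edges) == 0L) {
    edges <- data.frame(mirna_id = character(0), target_id = character(0),
                        target_class = character(0), pearson_r = numeric(0),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(need %in% colnames(edges)))
  if (is.null(nodes)) {
    nodes <- derive_nodes(edges)
  }
  structure(list(stage = stage, nodes = nodes,
                 edges = edges[need]),
            class = "cerna_network")
}

derive_nodes <- function(edges) {
  mir <- unique(edges$mirna_id)
  tgt <- unique(edges[c("target_id", "target_class")])
  nodes <- rbind(
    data.frame(id = mir, class = rep("miRNA", length(mir)),
               stringsAsFactors = FALSE),
    data.frame(id = tgt$target_id, class = tgt$target_class,
               stringsAsFactors = FALSE)
  )
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

#' @export
print.cerna_network <- function(x, ...) {
  tab <- table(factor(x$nodes$class, levels = c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf("cerna_network [%s]: %d lncRNA, %d miRNA, %d mRNA; %d edges\n",
              x$stage, tab[["lncRNA"]], tab[["miRNA"]], tab[["mRNA"]],
              nrow(x$edges)))
  invisible(x)
}

#' miRNA node ids of a network
#' @param network a `cerna_network`.
#' @return character vector.
#' @export
network_mirnas <- function(network) {
  network$nodes$id[network$nodes$class == "miRNA"]
}

#' Match differentially expressed miRNAs and targets through an interaction table
#'
#' Returns exactly the interaction rows whose miRNA and whose target are both
#' flagged `is_de` in the supplied DE table, annotated with both genes'
#' regulation directions. Rows whose target class disagrees with the DE
#' table's class for that gene are skipped with a warning.
#'
#' @param de_table combined DE table covering all three RNA classes
#'   (from [differential_all_classes()]).
#' @param interactions interaction data frame (mirna_id, target_id,
#'   target_class, source).
#' @return data frame of candidate pairs with `mirna_direction` and
#'   `target_direction` columns.
#' @export
match_targets <- function(de_table, interactions) {
  de <- de_table[de_table$is_de, , drop = FALSE]
  de_mir <- de$gene_id[de$class == "miRNA"]
  keep <- interactions$mirna_id %in% de_mir & interactions$target_id %in% de$gene_id
  cand <- interactions[keep, , drop = FALSE]
  if (nrow(cand) > 0L) {
    declass <- stats::setNames(de$class, de$gene_id)
    mismatch <- declass[cand$target_id] != cand$target_class
    if (any(mismatch)) {
      warning(sum(mismatch), " interaction row(s) with target class ",
              "inconsistent with the expression data; skipped")
      cand <- cand[!mismatch, , drop = FALSE]
    }
    dedir <- stats::setNames(de$direction, de$gene_id)
    cand$mirna_direction <- unname(dedir[cand$mirna_id])
    cand$target_direction <- unname(dedir[cand$target_id])
  } else {
    cand$mirna_direction <- character(0)
    cand$target_direction <- character(0)
  }
  rownames(cand) <- NULL
  cand
}

#' Pearson correlation of two expression vectors
#'
#' Plain sample Pearson correlation; returns `NA` (with a warning suppressed
#' at this level) when either vector is constant, signalling the caller to
#' exclude the pair.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
pairwise_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Build the ceRNA network of one stage
#'
#' For each candidate pair the miRNA and target expression vectors are paired
#' by sample-id intersection over the configured scope (tumour samples of the
#' stage, optionally plus normals), log2(x+1)-transformed, and correlated.
#' Pairs with correlation strictly below the (negative) threshold become
#' edges; pairs with undefined correlation or too few paired samples are
#' excluded and counted.
#'
#' @param candidates candidate pairs from [match_targets()] for this stage.
#' @param expression named list of linear-scale matrices by RNA class.
#' @param sample_table sample data frame.
#' @param stage stage label.
#' @param config a [network_config()].
#' @return a `cerna_network`; the number of skipped pairs (missing expression,
#'   constant vectors, too few samples) is attached as attribute `n_skipped`.
#' @export
build_stage_network <- function(candidates, expression, sample_table, stage,
                                config = network_config()) {
  scope_ids <- sample_table$sample_id[sample_table$group == stage]
  if (config$correlation_sample_scope == "tumor_plus_normal") {
    scope_ids <- c(scope_ids,
                   sample_table$sample_id[sample_table$group == "normal"])
  }
  mir_mat <- expression$miRNA
  n_skipped <- 0L
  keep <- logical(nrow(candidates))
  rvals <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    mi <- candidates$mirna_id[i]
    ti <- candidates$target_id[i]
    tmat <- expression[[candidates$target_class[i]]]
    if (is.null(tmat) || !(mi %in% rownames(mir_mat)) ||
        !(ti %in% rownames(tmat))) {
      n_skipped <- n_skipped + 1L
      next
    }
    common <- intersect(intersect(scope_ids, colnames(mir_mat)), colnames(tmat))
    if (length(common) < config$min_samples) {
      n_skipped <- n_skipped + 1L
      next
    }
    r <- pairwise_correlation(log2(mir_mat[mi, common] + 1),
                              log2(tmat[ti, common] + 1))
    if (is.na(r)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rvals[i] <- r
    keep[i] <- r < config$correlation_threshold
  }
  if (n_skipped > 0L)
    warning(n_skipped, " candidate pair(s) skipped (missing expression, ",
            "constant vectors, or < min_samples paired samples)")
  edges <- candidates[keep, c("mirna_id", "target_id", "target_class"),
                      drop = FALSE]
  edges$pearson_r <- rvals[keep]
  net <- cerna_network(stage, edges)
  attr(net, "n_skipped") <- n_skipped
  net
}

#' Validate the doubly bipartite structure of a network
#'
#' Checks that every edge joins a miRNA to a lncRNA or mRNA (no miRNA-miRNA,
#' lncRNA-lncRNA, mRNA-mRNA or lncRNA-mRNA edges), that no node plays both
#' the miRNA and the target role, and that every non-miRNA node has degree at
#' least one.
#'
#' @param network a `cerna_network`.
#' @return list with `pass` (logical) and `failures` (character vector
#'   describing each violation).
#' @export
validate_doubly_bipartite <- function(network) {
  failures <- character(0)
  e <- network$edges
  cls <- stats::setNames(network$nodes$class, network$nodes$id)

  bad_tc <- which(!e$target_class %in% c("lncRNA", "mRNA"))
  for (i in bad_tc)
    failures <- c(failures, sprintf(
      "edge %s--%s: forbidden target class '%s'",
      e$mirna_id[i], e$target_id[i], e$target_class[i]))

  bad_mir <- which(!is.na(cls[e$mirna_id]) & cls[e$mirna_id] != "miRNA")
  for (i in bad_mir)
    failures <- c(failures, sprintf(
      "edge %s--%s: source node is not a miRNA (class '%s')",
      e$mirna_id[i], e$target_id[i], cls[[e$mirna_id[i]]]))

  both_roles <- intersect(e$mirna_id, e$target_id)
  for (id in both_roles)
    failures <- c(failures, sprintf(
      "node %s appears both as miRNA and as target", id))

  non_mir <- network$nodes$id[network$nodes$class != "miRNA"]
  isolated <- setdiff(non_mir, e$target_id)
  for (id in isolated)
    failures <- c(failures, sprintf("non-miRNA node %s has degree 0", id))

  list(pass = length(failures) == 0L, failures = failures)
}
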