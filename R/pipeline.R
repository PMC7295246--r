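#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis in one place so a run is
#' fully described by its configuration (plus the input data): the DE filter,
#' the network correlation rule, the enrichment normalisation, the survival
#' split rule and alpha, and the stage list.
#'
#' @param de a [de_config()].
#' @param network a [network_config()].
#' @param eta_norm enrichment-efficiency normalisation, see [enrich()].
#' @param split_rule,split_q survival grouping rule, see
#'   [split_by_expression()].
#' @param alpha significance level of the survival screen.
#' @param stages stage labels analysed, default I-IV.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(de = de_config(),
                            network = network_config(),
                            eta_norm = "query_size",
                            split_rule = "median", split_q = 0.5,
                            alpha = 0.05,
                            stages = tumor_stages()) {
  stopifnot(inherits(de, "de_config"), inherits(network, "network_config"),
            !anyDuplicated(stages))
  structure(list(de = de, network = network, eta_norm = eta_norm,
                 split_rule = split_rule, split_q = split_q, alpha = alpha,
                 stages = stages),
            class = "pipeline_config")
}

#' Run the full stage-resolved ceRNA analysis
#'
#' Executes, for each stage: differential expression of all three RNA classes
#' versus normal, miRNA-target matching through the interaction table, and
#' negative-correlation network construction. The stage networks are then
#' partitioned into CCEN/UCENs, the mRNA compartments are tested for
#' annotation enrichment (with the enrichment-efficiency comparison across
#' compartment gene lists), and the CCEN miRNAs are screened for prognostic
#' value. A stage with no DE miRNAs yields an empty network with a warning
#' and the run continues.
#'
#' @param dataset a `cerna_dataset` (from [generate_dataset()] or
#'   [read_fixture()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when supplied, all tables and a JSON
#'   manifest are written there via [write_result_bundle()].
#' @return object of class `cerna_pipeline_result` with elements `de_tables`,
#'   `networks`, `partition`, `enrichment`, `efficiency`, `screen`,
#'   `manifest`, `config`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(dataset, "cerna_dataset"))
  stages <- config$stages

  de_tables <- stats::setNames(lapply(stages, function(s)
    differential_all_classes(dataset$expression, dataset$samples, s,
                             config$de)), stages)

  networks <- stats::setNames(lapply(stages, function(s) {
    det <- de_tables[[s]]
    if (!any(det$is_de & det$class == "miRNA")) {
      warning("stage ", s, ": no differentially expressed miRNAs; ",
              "emitting an empty network")
    }
    cand <- match_targets(det, dataset$interactions)
    build_stage_network(cand, dataset$expression, dataset$samples, s,
                        config$network)
  }), stages)

  partition <- partition_networks(networks)

  ## ---- enrichment over mRNA compartments ----------------------------------
  full_union <- extract_subnetwork(networks, unique(unlist(lapply(
    networks, network_mirnas))), mode = "union_edges", label = "ALL")
  ucen_mrnas <- unique(unlist(lapply(partition$ucen, mirna_linked_mrnas)))
  gene_lists <- list(
    CCEN = mirna_linked_mrnas(partition$ccen),
    UCEN = ucen_mrnas,
    CeRNA = mirna_linked_mrnas(full_union)
  )
  gene_lists <- gene_lists[vapply(gene_lists, length, 1L) > 0L]
  background <- unique(unlist(dataset$annotation$genes))
  enrichment <- lapply(gene_lists, function(g)
    suppressWarnings(enrich(g, dataset$annotation, background,
                            eta_norm = config$eta_norm)))
  efficiency <- if (length(gene_lists) >= 2L && length(background) > 0L) {
    suppressWarnings(compare_efficiency(gene_lists, dataset$annotation,
                                        background, eta_norm = config$eta_norm))
  } else NULL

  ## ---- survival screen of CCEN miRNAs -------------------------------------
  ccen_mirs <- intersect(partition$common_mirnas,
                         rownames(dataset$expression$miRNA))
  screen <- if (length(ccen_mirs) > 0L) {
    survival_screen(ccen_mirs, dataset$expression$miRNA, dataset$samples,
                    alpha = config$alpha, split_rule = config$split_rule,
                    split_q = config$split_q)
  } else NULL

  manifest <- build_manifest(dataset, config, de_tables, networks, partition,
                             gene_lists, screen)
  result <- structure(list(de_tables = de_tables, networks = networks,
                           partition = partition, enrichment = enrichment,
                           efficiency = efficiency, screen = screen,
                           manifest = manifest, config = config),
                      class = "cerna_pipeline_result")
  if (!is.null(out_dir)) write_result_bundle(result, out_dir)
  result
}

build_manifest <- function(dataset, config, de_tables, networks, partition,
                           gene_lists, screen) {
  stages <- config$stages
  de_counts <- lapply(de_tables, function(det) {
    tab <- table(det$class[det$is_de])
    lapply(c("lncRNA", "miRNA", "mRNA"), function(cl)
      if (cl %in% names(tab)) unname(tab[[cl]]) else 0L) |>
      stats::setNames(c("lncRNA", "miRNA", "mRNA"))
  })
  net_counts <- lapply(networks, function(net) {
    list(nodes = nrow(net$nodes), edges = nrow(net$edges),
         skipped_pairs = attr(net, "n_skipped"))
  })
  compartments <- partition_counts(partition)
  list(
    thresholds = list(
      log2fc_threshold = config$de$log2fc_threshold,
      p_threshold = config$de$p_threshold,
      correlation_threshold = config$network$correlation_threshold,
      correlation_sample_scope = config$network$correlation_sample_scope,
      eta_norm = config$eta_norm,
      alpha = config$alpha,
      split_rule = config$split_rule
    ),
    n_samples = as.list(table(dataset$samples$group)),
    de_genes = de_counts,
    networks = net_counts,
    compartments = compartments,
    shared_mirnas = length(partition$shared_mirnas),
    gene_list_sizes = lapply(gene_lists, length),
    screened_mirnas = if (is.null(screen)) 0L else
      length(unique(screen$screen$mirna_id))
  )
}

#' Write a pipeline result bundle to a directory
#'
#' Emits per-stage DE tables and network edge lists, CCEN/UCEN edge lists,
#' the membership table, enrichment tables, the efficiency comparison, the
#' survival screen and a JSON manifest — all as TSV/JSON text files written
#' atomically.
#'
#' @param result a `cerna_pipeline_result`.
#' @param out_dir output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
write_result_bundle <- function(result, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", out_dir)
  wtsv <- function(df, name) {
    path <- file.path(out_dir, name)
    lines <- c(paste(colnames(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                              sep = "\t")))
    atomic_write(lines, path)
  }
  for (s in names(result$de_tables))
    wtsv(result$de_tables[[s]], sprintf("de_stage_%s.tsv", s))
  for (s in names(result$networks))
    wtsv(edge_table(result$networks[[s]]), sprintf("network_stage_%s.tsv", s))
  wtsv(edge_table(result$partition$ccen), "network_CCEN.tsv")
  for (s in names(result$partition$ucen))
    wtsv(edge_table(result$partition$ucen[[s]]), sprintf("network_UCEN_%s.tsv", s))
  wtsv(result$partition$membership, "membership.tsv")
  for (nm in names(result$enrichment))
    wtsv(result$enrichment[[nm]], sprintf("enrichment_%s.tsv", nm))
  if (!is.null(result$efficiency)) {
    wtsv(result$efficiency$table, "efficiency_long.tsv")
    wtsv(data.frame(list = names(result$efficiency$mean_eta),
                    mean_eta = unname(result$efficiency$mean_eta)),
         "efficiency_mean.tsv")
  }
  if (!is.null(result$screen)) {
    wtsv(result$screen$screen, "survival_screen.tsv")
    wtsv(result$screen$classification, "survival_classification.tsv")
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}

edge_table <- function(network) {
  e <- network$edges
  if (nrow(e) == 0L) {
    return(data.frame(stage = character(0), mirna_id = character(0),
                      target_id = character(0), target_class = character(0),
                      pearson_r = numeric(0), stringsAsFactors = FALSE))
  }
  cbind(data.frame(stage = network$stage, stringsAsFactors = FALSE), e)
}

#' @export
print.cerna_pipeline_result <- function(x, ...) {
  cat("ceRNA pipeline result\n")
  for (s in names(x$networks)) {
    det <- x$de_tables[[s]]
    cat(sprintf("  stage %s: %d DE genes, %d network edges\n", s,
                sum(det$is_de), nrow(x$networks[[s]]$edges)))
  }
  print(x$partition)
  if (!is.null(x$screen)) print(x$screen)
  invisible(x)
}
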