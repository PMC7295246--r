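#' miRNAs common to every stage network
#'
#' Set intersection of the miRNA node sets of all supplied networks — the
#' miRNA membership that defines the common network (CCEN).
#'
#' @param networks list of at least two `cerna_network` objects.
#' @return character vector of miRNA ids.
#' @export
common_mirnas <- function(networks) {
  if (length(networks) < 2L) stop("need at least two networks")
  Reduce(intersect, lapply(networks, network_mirnas))
}

#' miRNAs unique to one stage network
#'
#' miRNAs present in the named stage's network and in no other supplied
#' network — the membership that defines that stage's unique network (UCEN).
#'
#' @param networks named list of `cerna_network` objects (names are stages).
#' @param stage the stage whose unique miRNAs are wanted.
#' @return character vector of miRNA ids.
#' @export
unique_mirnas <- function(networks, stage) {
  if (!stage %in% names(networks)) stop("unknown stage: ", stage)
  others <- networks[names(networks) != stage]
  setdiff(network_mirnas(networks[[stage]]),
          unique(unlist(lapply(others, network_mirnas))))
}

#' Extract the subnetwork induced by a miRNA set
#'
#' Collects the edges incident to `mirna_set` from the union of all stage
#' networks (`mode = "union_edges"`, the CCEN convention) or from one named
#' stage only (`mode = "single_stage"`, the UCEN convention). When the same
#' miRNA-target pair occurs in several stage networks with different
#' correlations, the most negative correlation is kept.
#'
#' @param networks named list of `cerna_network` objects.
#' @param mirna_set character vector of miRNA ids (may be empty).
#' @param mode `"union_edges"` or `"single_stage"`.
#' @param stage required when `mode = "single_stage"`.
#' @param label stage label of the returned network.
#' @return a `cerna_network`.
#' @export
extract_subnetwork <- function(networks, mirna_set,
                               mode = c("union_edges", "single_stage"),
                               stage = NULL, label = NULL) {
  mode <- match.arg(mode)
  if (mode == "single_stage") {
    if (is.null(stage) || !stage %in% names(networks))
      stop("single_stage mode needs a stage present among the networks")
    pool <- networks[[stage]]$edges
    if (is.null(label)) label <- paste0("UCEN-", stage)
  } else {
    pool <- do.call(rbind, lapply(networks, `[[`, "edges"))
    if (is.null(label)) label <- "CCEN"
  }
  if (is.null(pool) || nrow(pool) == 0L || length(mirna_set) == 0L) {
    return(cerna_network(label, pool[0, , drop = FALSE]))
  }
  pool <- pool[pool$mirna_id %in% mirna_set, , drop = FALSE]
  # collapse duplicates across stages, keeping the strongest anti-correlation
  pool <- pool[order(pool$pearson_r), , drop = FALSE]
  key <- paste(pool$mirna_id, pool$target_id, sep = "\r")
  pool <- pool[!duplicated(key), , drop = FALSE]
  rownames(pool) <- NULL
  cerna_network(label, pool)
}

#' mRNAs linked to at least one miRNA in a network
#'
#' @param network a `cerna_network`.
#' @return character vector of mRNA ids with a miRNA neighbour.
#' @export
mirna_linked_mrnas <- function(network) {
  e <- network$edges
  unique(e$target_id[e$target_class == "mRNA"])
}

#' Partition stage networks into CCEN, UCENs and the shared middle class
#'
#' The common network (CCEN) is induced by miRNAs present in every stage
#' network; each unique network (UCEN) by miRNAs present in exactly one.
#' miRNAs appearing in two or three stage networks belong to neither
#' compartment and are reported as "shared". The membership table classifies
#' every node of the union of stage networks.
#'
#' @param networks named list of `cerna_network` objects, one per stage.
#' @return object of class `partition_result`: `ccen`, `ucen` (named list),
#'   `common_mirnas`, `unique_mirnas` (named list), `shared_mirnas`,
#'   `membership` (data frame gene_id, class, compartment).
#' @export
partition_networks <- function(networks) {
  stopifnot(length(networks) >= 2L, !is.null(names(networks)))
  stages <- names(networks)
  common <- common_mirnas(networks)
  uniq <- stats::setNames(lapply(stages, function(s)
    unique_mirnas(networks, s)), stages)

  ccen <- extract_subnetwork(networks, common, mode = "union_edges")
  ucen <- stats::setNames(lapply(stages, function(s)
    extract_subnetwork(networks, uniq[[s]], mode = "single_stage", stage = s)),
    stages)

  all_mirnas <- unique(unlist(lapply(networks, network_mirnas)))
  shared <- setdiff(all_mirnas, c(common, unlist(uniq)))

  membership <- partition_membership(networks, ccen, ucen, shared)

  structure(list(ccen = ccen, ucen = ucen,
                 common_mirnas = common, unique_mirnas = uniq,
                 shared_mirnas = shared, membership = membership),
            class = "partition_result")
}

partition_membership <- function(networks, ccen, ucen, shared) {
  union_nodes <- do.call(rbind, lapply(networks, `[[`, "nodes"))
  union_nodes <- union_nodes[!duplicated(union_nodes$id), , drop = FALSE]
  rows <- list()
  add <- function(ids, compartment) {
    if (length(ids) == 0L) return()
    cls <- stats::setNames(union_nodes$class, union_nodes$id)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = ids, class = unname(cls[ids]),
      compartment = compartment, stringsAsFactors = FALSE)
  }
  add(ccen$nodes$id, "CCEN")
  for (s in names(ucen)) add(ucen[[s]]$nodes$id, paste0("UCEN-", s))
  add(shared, "shared")
  mem <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), class = character(0),
               compartment = character(0), stringsAsFactors = FALSE)
  leftover <- setdiff(union_nodes$id, mem$gene_id)
  if (length(leftover)) {
    cls <- stats::setNames(union_nodes$class, union_nodes$id)
    mem <- rbind(mem, data.frame(gene_id = leftover,
                                 class = unname(cls[leftover]),
                                 compartment = "neither",
                                 stringsAsFactors = FALSE))
  }
  rownames(mem) <- NULL
  mem
}

#' @export
print.partition_result <- function(x, ...) {
  cat("ceRNA network partition\n")
  cat(sprintf("  CCEN: %d common miRNAs, %d nodes, %d edges\n",
              length(x$common_mirnas), nrow(x$ccen$nodes), nrow(x$ccen$edges)))
  for (s in names(x$ucen)) {
    cat(sprintf("  UCEN-%s: %d unique miRNAs, %d nodes, %d edges\n", s,
                length(x$unique_mirnas[[s]]), nrow(x$ucen[[s]]$nodes),
                nrow(x$ucen[[s]]$edges)))
  }
  cat(sprintf("  shared (2-3 stages) miRNAs: %d\n", length(x$shared_mirnas)))
  invisible(x)
}

#' Per-compartment node counts by RNA class
#' @param partition a `partition_result`.
#' @return data frame: compartment, lncRNA, miRNA, mRNA counts.
#' @export
partition_counts <- function(partition) {
  nets <- c(list(CCEN = partition$ccen), stats::setNames(
    partition$ucen, paste0("UCEN-", names(partition$ucen))))
  do.call(rbind, lapply(names(nets), function(nm) {
    tab <- table(factor(nets[[nm]]$nodes$class,
                        levels = c("lncRNA", "miRNA", "mRNA")))
    data.frame(compartment = nm, lncRNA = tab[["lncRNA"]],
               miRNA = tab[["miRNA"]], mRNA = tab[["mRNA"]],
               stringsAsFactors = FALSE)
  }))
}
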