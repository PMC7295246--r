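#' Upper-tail hypergeometric p-value for over-representation
#'
#' Probability of observing at least `k` annotated genes in a draw of `n`
#' genes from a background of `N` genes of which `M` are annotated:
#' `P(X >= k) = sum_{i=k}^{min(M,n)} C(M,i) C(N-M,n-i) / C(N,n)`,
#' equivalently one minus the lower sum up to `k - 1`. The sum is accumulated
#' in log space via `lchoose` for numerical stability and the result is
#' clamped to `(0, 1]`.
#'
#' @param N background size.
#' @param M annotated genes in the background.
#' @param n query-list size.
#' @param k annotated genes in the query list.
#' @return the upper-tail p-value in `(0, 1]`.
#' @export
hypergeom_p <- function(N, M, n, k) {
  stopifnot(length(N) == 1L, length(M) == 1L, length(n) == 1L, length(k) == 1L)
  if (M > N || n > N || k < 0 || k > min(M, n))
    stop("require 0 <= k <= min(M, n), M <= N, n <= N")
  if (k == 0) return(1)
  i <- k:min(M, n)
  logterms <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  m <- max(logterms)
  p <- exp(m + log(sum(exp(logterms - m))))
  min(max(p, .Machine$double.xmin), 1)
}

#' Enrichment efficiency
#'
#' Normalises the enrichment signal by the size of the analysed gene list:
#' `eta = -log10(p) / list_size`. This makes enrichment comparable between
#' gene lists of very different sizes, rewarding small lists that carry the
#' same annotation signal as larger ones.
#'
#' @param p p-value in (0, 1].
#' @param list_size positive integer, the size of the analysed gene list.
#' @return eta, a non-negative real.
#' @export
enrichment_efficiency <- function(p, list_size) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  if (any(list_size < 1)) stop("list_size must be >= 1")
  -log10(p) / list_size
}

#' Hypergeometric over-representation test of a gene list
#'
#' One test per annotation term with at least one query hit (`k >= 1`; terms
#' with `k = 0` have upper-tail p = 1 and are omitted). The background
#' defaults to all annotated genes. Query genes outside the background are
#' dropped with a warning. A Benjamini-Hochberg adjusted column is emitted
#' for convenience but plays no role in the efficiency statistic.
#'
#' @param query_genes character vector of gene ids.
#' @param annotation an [annotation_table()].
#' @param background character vector of background gene ids; default: the
#'   union of all annotated genes.
#' @param eta_norm list size used to normalise eta: the query size (default)
#'   or the background size.
#' @return data frame sorted by p ascending: term_id, term_name, N, M, n, k,
#'   p, neg_log10_p, eta, p_adjust.
#' @export
enrich <- function(query_genes, annotation,
                   background = unique(unlist(annotation$genes)),
                   eta_norm = c("query_size", "background_size")) {
  eta_norm <- match.arg(eta_norm)
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  query <- unique(query_genes)
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped")
    query <- intersect(query, background)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(seq_along(annotation$term_id), function(j) {
    members <- intersect(annotation$genes[[j]], background)
    M <- length(members)
    k <- length(intersect(members, query))
    if (k == 0L) return(NULL)
    p <- hypergeom_p(N, M, n, k)
    size <- if (eta_norm == "query_size") n else N
    data.frame(term_id = annotation$term_id[j],
               term_name = annotation$term_name[j],
               N = N, M = M, n = n, k = k, p = p,
               neg_log10_p = -log10(p),
               eta = enrichment_efficiency(p, size),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      N = integer(0), M = integer(0), n = integer(0),
                      k = integer(0), p = numeric(0),
                      neg_log10_p = numeric(0), eta = numeric(0),
                      p_adjust = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  out$p_adjust <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Compare enrichment efficiency across gene lists
#'
#' Runs the over-representation test for each named list against the same
#' annotation and background, and tabulates p and eta per (list, term) —
#' including terms with no hit in a list (p = 1, eta = 0) so lists are
#' compared on a common term grid. Also reports each list's mean eta over a
#' chosen term subset.
#'
#' @param gene_lists named list of character vectors (at least two).
#' @param annotation an [annotation_table()].
#' @param background background gene ids.
#' @param terms term ids over which the mean eta is taken; default: all terms.
#' @param eta_norm passed to [enrich()].
#' @return list with `table` (list, term_id, p, neg_log10_p, eta) and
#'   `mean_eta` (named numeric, one entry per list, sorted decreasing).
#' @export
compare_efficiency <- function(gene_lists, annotation,
                               background = unique(unlist(annotation$genes)),
                               terms = annotation$term_id,
                               eta_norm = c("query_size", "background_size")) {
  eta_norm <- match.arg(eta_norm)
  stopifnot(length(gene_lists) >= 2L, !is.null(names(gene_lists)))
  if (any(vapply(gene_lists, length, 1L) == 0L))
    stop("every gene list must be non-empty")
  rows <- lapply(names(gene_lists), function(nm) {
    res <- enrich(gene_lists[[nm]], annotation, background, eta_norm)
    idx <- match(annotation$term_id, res$term_id)
    p <- ifelse(is.na(idx), 1, res$p[idx])
    eta <- ifelse(is.na(idx), 0, res$eta[idx])
    data.frame(list = nm, term_id = annotation$term_id, p = p,
               neg_log10_p = -log10(p), eta = eta, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sub <- tab[tab$term_id %in% terms, , drop = FALSE]
  mean_eta <- vapply(split(sub$eta, sub$list), mean, numeric(1))
  mean_eta <- sort(mean_eta[names(gene_lists)], decreasing = TRUE)
  list(table = tab, mean_eta = mean_eta)
}

#' Terms-by-lists matrix of -log10 p, the heat-map layout
#' @param comparison result of [compare_efficiency()].
#' @return numeric matrix, terms in rows, gene lists in columns.
#' @export
efficiency_matrix <- function(comparison) {
  tab <- comparison$table
  terms <- unique(tab$term_id)
  lists <- unique(tab$list)
  m <- matrix(NA_real_, length(terms), length(lists),
              dimnames = list(terms, lists))
  m[cbind(match(tab$term_id, terms), match(tab$list, lists))] <- tab$neg_log10_p
  m
}
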