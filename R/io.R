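#' Annotation catalogue (gene sets)
#'
#' A small container for GMT-style gene sets: parallel vectors of term ids and
#' names plus a list of member gene-id vectors.
#'
#' @param term_id character vector of unique term identifiers.
#' @param term_name character vector of human-readable names.
#' @param genes list of character vectors, one per term; member sets must be
#'   non-empty.
#' @return object of class `annotation_table`.
#' @export
annotation_table <- function(term_id, term_name, genes) {
  stopifnot(length(term_id) == length(term_name),
            length(term_id) == length(genes))
  if (anyDuplicated(term_id)) stop("term ids must be unique")
  if (length(genes) > 0L && any(vapply(genes, length, 1L) == 0L))
    stop("annotation member sets must be non-empty")
  genes <- lapply(genes, function(g) unique(as.character(g)))
  structure(list(term_id = as.character(term_id),
                 term_name = as.character(term_name),
                 genes = stats::setNames(genes, term_id)),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("annotation_table: %d terms, %d distinct genes\n",
              length(x$term_id), length(unique(unlist(x$genes)))))
  invisible(x)
}

# write a file atomically: temp file in the same directory, then rename
atomic_write <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

# doubles formatted with 17 significant digits round-trip exactly
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write an expression matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample. Values are
#' written with enough digits to round-trip IEEE doubles exactly.
#'
#' @param mat numeric matrix, genes x samples, with dimnames.
#' @param path output file.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  header <- paste(c("gene_id", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = "\t")
  }, character(1))
  atomic_write(c(header, body), path)
}

#' Read an expression TSV written by [write_expression_tsv()]
#' @param path input file.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  if (colnames(df)[1] != "gene_id")
    stop("expression file ", path, ": first column must be 'gene_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("expression file ", path, ": non-numeric values")
  rownames(m) <- df$gene_id
  m
}

#' Write / read the sample table (sample_id, group, time, event)
#' @param samples data frame with the four columns above.
#' @param path file path.
#' @export
write_sample_tsv <- function(samples, path) {
  need <- c("sample_id", "group", "time", "event")
  stopifnot(all(need %in% colnames(samples)))
  header <- paste(need, collapse = "\t")
  body <- paste(samples$sample_id, samples$group, fmt_num(samples$time),
                samples$event, sep = "\t")
  atomic_write(c(header, body), path)
}

#' @rdname write_sample_tsv
#' @export
read_sample_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample file ", path, ": missing columns ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample file ", path, ": duplicate sample ids")
  bad <- which(!df$group %in% c("normal", tumor_stages()))
  if (length(bad)) stop("sample file ", path, ": unknown group at data line ",
                        bad[1], ": '", df$group[bad[1]], "'")
  df$event <- as.integer(df$event)
  df
}

#' Write / read a miRNA-target interaction table
#'
#' On read, duplicate (mirna_id, target_id) rows are collapsed into one with
#' their sources concatenated (`;`-separated), with a warning.
#'
#' @param interactions data frame: mirna_id, target_id, target_class, source.
#' @param path file path.
#' @export
write_interaction_tsv <- function(interactions, path) {
  need <- c("mirna_id", "target_id", "target_class", "source")
  stopifnot(all(need %in% colnames(interactions)))
  header <- paste(need, collapse = "\t")
  body <- do.call(paste, c(interactions[need], sep = "\t"))
  atomic_write(c(header, body), path)
}

#' @rdname write_interaction_tsv
#' @export
read_interaction_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id", "target_class", "source")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("interaction file ", path, ": missing columns ",
                         paste(miss, collapse = ", "))
  bad <- which(!df$target_class %in% c("lncRNA", "mRNA"))
  if (length(bad)) stop("interaction file ", path, ": invalid target_class at data line ",
                        bad[1], ": '", df$target_class[bad[1]], "'")
  dedupe_interactions(df)
}

#' Collapse duplicate interaction rows, merging sources
#' @param df interaction data frame.
#' @return deduplicated data frame.
#' @export
dedupe_interactions <- function(df) {
  key <- paste(df$mirna_id, df$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning(n_dup, " duplicate interaction pair(s) collapsed; sources merged")
    src <- vapply(split(df$source, key), function(s)
      paste(unique(s), collapse = ";"), character(1))
    df <- df[!duplicated(key), , drop = FALSE]
    df$source <- unname(src[paste(df$mirna_id, df$target_id, sep = "\r")])
  }
  rownames(df) <- NULL
  df
}

#' Write / read gene sets in GMT format
#'
#' Each line: term id, description, then tab-separated member gene ids. An
#' empty catalogue yields a valid empty file.
#'
#' @param annotation an [annotation_table()].
#' @param path file path.
#' @export
write_gmt <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_table"))
  lines <- vapply(seq_along(annotation$term_id), function(i) {
    paste(c(annotation$term_id[i], annotation$term_name[i],
            annotation$genes[[i]]), collapse = "\t")
  }, character(1))
  atomic_write(lines, path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(annotation_table(character(0), character(0), list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short)) stop("GMT file ", path, ": line ", short[1],
                          " has fewer than 3 fields")
  annotation_table(
    term_id = vapply(parts, `[[`, character(1), 1L),
    term_name = vapply(parts, `[[`, character(1), 2L),
    genes = lapply(parts, function(p) p[-c(1L, 2L)])
  )
}

#' Write a synthetic dataset to a fixture directory
#'
#' Emits `expression_<class>.tsv` for each RNA class, `samples.tsv`,
#' `interactions.tsv`, `annotation.gmt` and `truth.json`. Reading the
#' directory back with [read_fixture()] reproduces the in-memory dataset
#' exactly (numeric values round-trip bit-for-bit).
#'
#' @param dataset a `cerna_dataset` from [generate_dataset()].
#' @param directory output directory, created if absent.
#' @return the directory, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "cerna_dataset"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", directory)
  for (cl in names(dataset$expression)) {
    write_expression_tsv(dataset$expression[[cl]],
                         file.path(directory, paste0("expression_", cl, ".tsv")))
  }
  write_sample_tsv(dataset$samples, file.path(directory, "samples.tsv"))
  write_interaction_tsv(dataset$interactions,
                        file.path(directory, "interactions.tsv"))
  write_gmt(dataset$annotation, file.path(directory, "annotation.gmt"))
  truth <- dataset$truth
  truth$de_genes <- as.list(truth$de_genes)
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       dataframe = "columns", auto_unbox = FALSE, digits = NA)
  invisible(directory)
}

#' Read a fixture directory back into a `cerna_dataset`
#' @param directory directory written by [write_fixture()].
#' @return a `cerna_dataset` (without the generating `config`).
#' @export
read_fixture <- function(directory) {
  classes <- c("lncRNA", "miRNA", "mRNA")
  expression <- stats::setNames(lapply(classes, function(cl) {
    read_expression_tsv(file.path(directory, paste0("expression_", cl, ".tsv")))
  }), classes)
  samples <- read_sample_tsv(file.path(directory, "samples.tsv"))
  interactions <- read_interaction_tsv(file.path(directory, "interactions.tsv"))
  annotation <- read_gmt(file.path(directory, "annotation.gmt"))
  tr <- jsonlite::read_json(file.path(directory, "truth.json"),
                            simplifyVector = TRUE)
  truth <- list(
    triples = as.data.frame(tr$triples, stringsAsFactors = FALSE),
    planted_pairs = as.data.frame(tr$planted_pairs, stringsAsFactors = FALSE),
    de_genes = lapply(tr$de_genes, as.character),
    enriched_terms = as.character(tr$enriched_terms),
    prognostic = as.data.frame(tr$prognostic, stringsAsFactors = FALSE)
  )
  structure(list(expression = expression, samples = samples,
                 interactions = interactions, annotation = annotation,
                 truth = truth, config = NULL),
            class = "cerna_dataset")
}
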