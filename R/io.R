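#' Write a view to disk
#'
#' Persists a view as a MatrixMarket coordinate file plus two label files
#' (row gene ids, column term ids) and a small JSON sidecar carrying the
#' name and weighting.
#'
#' @param view A [view()].
#' @param dir Output directory (created if missing).
#' @param name Base file name; defaults to the view name.
#' @return Invisibly, the paths written.
#' @export
write_view <- function(view, dir, name = view$name) {
  stopifnot(inherits(view, "mvtm_view"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, name)
  m <- methods::as(methods::as(Matrix::Matrix(view$weights, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paste0(base, ".mtx"))
  writeLines(view$gene_ids, paste0(base, ".genes.tsv"))
  writeLines(view$term_ids, paste0(base, ".terms.tsv"))
  jsonlite::write_json(
    list(name = view$name, weighting = view$weighting,
         n_genes = length(view$gene_ids), n_terms = length(view$term_ids)),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(base, c(".mtx", ".genes.tsv", ".terms.tsv", ".json")))
}

#' Read a view written by [write_view()]
#'
#' @param dir Directory holding the files.
#' @param name Base file name.
#' @return A [view()].
#' @export
read_view <- function(dir, name) {
  base <- file.path(dir, name)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  w <- Matrix::readMM(paste0(base, ".mtx"))
  genes <- readLines(paste0(base, ".genes.tsv"))
  terms <- readLines(paste0(base, ".terms.tsv"))
  view(meta$name, w, genes, terms, weighting = meta$weighting)
}

#' Write a corpus as TSV files
#'
#' Two files: `<name>.docs.tsv` with columns `doc_id`, `term`, `count`,
#' and `<name>.genemap.tsv` with columns `gene_id`, `doc_id`.
#'
#' @param corpus A [corpus()].
#' @param dir Output directory.
#' @param name Base file name.
#' @return Invisibly, the paths written.
#' @export
write_corpus <- function(corpus, dir, name = "corpus") {
  stopifnot(inherits(corpus, "mvtm_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trip <- corpus_triplets(corpus)
  names(trip) <- c("doc_id", "term", "count")
  docs_path <- file.path(dir, paste0(name, ".docs.tsv"))
  write.table(trip, docs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- data.frame(
    gene_id = rep(names(corpus$gene_doc_map),
                  lengths(corpus$gene_doc_map)),
    doc_id = unlist(corpus$gene_doc_map, use.names = FALSE)
  )
  map_path <- file.path(dir, paste0(name, ".genemap.tsv"))
  write.table(gm, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(docs_path, map_path))
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir Directory holding the files.
#' @param name Base file name.
#' @return A [corpus()].
#' @export
read_corpus <- function(dir, name = "corpus") {
  trip <- read.delim(file.path(dir, paste0(name, ".docs.tsv")),
                     colClasses = c("character", "character", "integer"))
  gm <- read.delim(file.path(dir, paste0(name, ".genemap.tsv")),
                   colClasses = "character")
  docs <- lapply(split(trip[c("term", "count")], trip$doc_id), function(d) {
    stats::setNames(as.integer(d$count), d$term)
  })
  # documents with no terms still exist if referenced by the map
  extra <- setdiff(unique(gm$doc_id), names(docs))
  if (length(extra)) {
    docs <- c(docs, stats::setNames(
      replicate(length(extra), stats::setNames(integer(0), character(0)),
                simplify = FALSE), extra))
  }
  map <- split(gm$doc_id, gm$gene_id)
  corpus(docs, map)
}

#' Write or read a vocabulary (one term per line, UTF-8)
#'
#' @param vocab A [vocabulary()].
#' @param path File path.
#' @return `write_vocabulary()` returns the path invisibly;
#'   `read_vocabulary()` returns a [vocabulary()].
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "mvtm_vocabulary"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(vocab$terms, con)
  invisible(path)
}

#' @rdname write_vocabulary
#' @param name Vocabulary name for `read_vocabulary()`.
#' @export
read_vocabulary <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  vocabulary(name, readLines(path, encoding = "UTF-8"))
}

#' Export a ranking list as TSV
#'
#' @param ranking An [rank_candidates()] tibble (optionally with a
#'   `p_value` column).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
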