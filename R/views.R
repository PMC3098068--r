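#' Controlled vocabulary
#'
#' A fixed list of lowercased terms used to index a document corpus. Each
#' vocabulary defines one "view" of the gene set: indexing the same corpus
#' with different vocabularies yields different gene-by-term matrices over
#' the same genes.
#'
#' @param name Short identifier.
#' @param terms Character vector of unique terms; must be non-empty.
#' @param parent Optional name of the complete vocabulary this is a subset of.
#' @return An object of class `mvtm_vocabulary`.
#' @export
vocabulary <- function(name, terms, parent = NULL) {
  terms <- as.character(terms)
  if (length(terms) == 0) stop("A vocabulary must be non-empty.", call. = FALSE)
  if (anyDuplicated(terms)) stop("Vocabulary terms must be unique.", call. = FALSE)
  structure(list(name = name, terms = terms, parent = parent),
            class = "mvtm_vocabulary")
}

#' @export
print.mvtm_vocabulary <- function(x, ...) {
  cat("<vocabulary '", x$name, "': ", length(x$terms), " terms",
      if (!is.null(x$parent)) paste0(", subset of '", x$parent, "'"),
      ">\n", sep = "")
  invisible(x)
}

#' Document corpus with gene-document links
#'
#' Holds a bag-of-terms per document together with the map assigning
#' documents to genes (the synthetic analogue of curated gene-to-publication
#' links such as GeneRIF).
#'
#' @param documents Named list; each element a named non-negative integer
#'   vector of term counts for one document.
#' @param gene_doc_map Named list; each element a character vector of
#'   document ids linked to one gene. Every referenced document must exist.
#' @return An object of class `mvtm_corpus`.
#' @export
corpus <- function(documents, gene_doc_map) {
  if (is.null(names(documents)) || anyDuplicated(names(documents))) {
    stop("Documents must have unique names.", call. = FALSE)
  }
  refd <- unique(unlist(gene_doc_map, use.names = FALSE))
  missing <- setdiff(refd, names(documents))
  if (length(missing) > 0) {
    stop("gene_doc_map references unknown documents: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  for (d in documents) {
    if (length(d) && (is.null(names(d)) || any(d < 0))) {
      stop("Each document is a named vector of non-negative counts.",
           call. = FALSE)
    }
  }
  structure(list(documents = documents, gene_doc_map = gene_doc_map),
            class = "mvtm_corpus")
}

#' @export
print.mvtm_corpus <- function(x, ...) {
  cat("<corpus: ", length(x$documents), " documents, ",
      length(x$gene_doc_map), " genes>\n", sep = "")
  invisible(x)
}

#' Gene-by-term view
#'
#' One controlled-vocabulary perspective on a common gene set: a genes x
#' terms weight matrix, in raw counts or IDF weighting.
#'
#' @param name View identifier.
#' @param weights Matrix (base or `Matrix`) with one row per gene.
#' @param gene_ids,term_ids Row and column identities; must match `dim(weights)`.
#' @param weighting `"count"` or `"idf"`; `"latent"` marks LSI-projected views.
#' @return An object of class `mvtm_view`.
#' @export
view <- function(name, weights, gene_ids, term_ids,
                 weighting = c("count", "idf", "latent")) {
  weighting <- match.arg(weighting)
  if (nrow(weights) != length(gene_ids) || ncol(weights) != length(term_ids)) {
    stop("View dimensions do not match the id lists.", call. = FALSE)
  }
  if (weighting == "count" && min(weights) < 0) {
    stop("Count-weighted views must be non-negative.", call. = FALSE)
  }
  dimnames(weights) <- list(gene_ids, term_ids)
  structure(list(name = name, gene_ids = as.character(gene_ids),
                 term_ids = as.character(term_ids), weights = weights,
                 weighting = weighting),
            class = "mvtm_view")
}

#' @export
print.mvtm_view <- function(x, ...) {
  cat("<view '", x$name, "': ", length(x$gene_ids), " genes x ",
      length(x$term_ids), " terms, ", x$weighting, " weighting>\n", sep = "")
  invisible(x)
}

#' @export
dim.mvtm_view <- function(x) dim(x$weights)

view_matrix <- function(v) as.matrix(v$weights)

#' Multi-view dataset
#'
#' A list of views sharing one gene ordering, plus the disease labels of the
#' benchmark genes. Genes may carry more than one disease label; unlabeled
#' genes form the candidate pool for prioritization.
#'
#' @param views List of [view()] objects with identical `gene_ids`.
#' @param labels Named list mapping labeled gene ids to character vectors of
#'   disease ids.
#' @return An object of class `mvtm_dataset`.
#' @export
multiview_dataset <- function(views, labels) {
  if (length(views) < 1) stop("At least one view is required.", call. = FALSE)
  g0 <- views[[1]]$gene_ids
  for (v in views) {
    if (!identical(v$gene_ids, g0)) {
      stop("All views must share an identical gene ordering.", call. = FALSE)
    }
  }
  if (length(labels) && !all(names(labels) %in% g0)) {
    stop("Every labeled gene must appear in every view.", call. = FALSE)
  }
  names(views) <- vapply(views, function(v) v$name, character(1))
  structure(list(views = views, labels = labels, gene_ids = g0,
                 n_views = length(views)),
            class = "mvtm_dataset")
}

#' @export
print.mvtm_dataset <- function(x, ...) {
  cat("<multi-view dataset: ", x$n_views, " views, ", length(x$gene_ids),
      " genes (", length(x$labels), " labeled)>\n", sep = "")
  invisible(x)
}

#' Disease labels as a tibble
#'
#' @param dataset A [multiview_dataset()].
#' @return Tibble with columns `gene_id`, `disease`.
#' @export
label_table <- function(dataset) {
  tibble::tibble(
    gene_id = rep(names(dataset$labels),
                  lengths(dataset$labels)),
    disease = unlist(dataset$labels, use.names = FALSE)
  )
}

corpus_triplets <- function(corpus) {
  docs <- corpus$documents
  nterm <- lengths(docs)
  data.frame(
    doc = rep(names(docs), nterm),
    term = unlist(lapply(docs, names), use.names = FALSE),
    count = unlist(docs, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Index a corpus with a controlled vocabulary
#'
#' Counts the occurrences of each vocabulary term in each document; tokens
#' absent from the vocabulary are ignored. This is the per-view indexing step
#' of the text-mining pipeline.
#'
#' @param corpus A [corpus()].
#' @param vocab A [vocabulary()].
#' @return A sparse document-by-term count matrix
#'   (`Matrix::dgCMatrix`) with document and term dimnames.
#' @export
index_corpus <- function(corpus, vocab) {
  stopifnot(inherits(corpus, "mvtm_corpus"), inherits(vocab, "mvtm_vocabulary"))
  doc_ids <- names(corpus$documents)
  trip <- corpus_triplets(corpus)
  trip <- trip[trip$term %in% vocab$terms & trip$count > 0, , drop = FALSE]
  Matrix::sparseMatrix(
    i = match(trip$doc, doc_ids),
    j = match(trip$term, vocab$terms),
    x = as.numeric(trip$count),
    dims = c(length(doc_ids), length(vocab$terms)),
    dimnames = list(doc_ids, vocab$terms)
  )
}

#' Average document profiles into gene profiles
#'
#' A gene's term profile is the arithmetic mean of the indexed profiles of
#' its mapped documents. Genes with no mapped documents get an all-zero row
#' and are flagged in the `zero_genes` attribute; such genes are excluded
#' from model training downstream but may appear as ranking candidates.
#'
#' @param doc_term Document-by-term matrix from [index_corpus()].
#' @param gene_doc_map Named list mapping gene ids to document id vectors.
#' @param name Name for the resulting view.
#' @return A count-weighted [view()] with attribute `zero_genes`.
#' @export
aggregate_gene_profiles <- function(doc_term, gene_doc_map, name = "view") {
  gene_ids <- names(gene_doc_map)
  unknown <- setdiff(unique(unlist(gene_doc_map, use.names = FALSE)),
                     rownames(doc_term))
  if (length(unknown) > 0) {
    stop("gene_doc_map references documents without indexed rows: ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  ndoc <- lengths(gene_doc_map)
  # gene-by-doc averaging operator, sparse
  A <- Matrix::sparseMatrix(
    i = rep(seq_along(gene_ids), ndoc),
    j = match(unlist(gene_doc_map, use.names = FALSE), rownames(doc_term)),
    x = rep(1 / pmax(ndoc, 1), ndoc),
    dims = c(length(gene_ids), nrow(doc_term))
  )
  w <- A %*% doc_term
  out <- view(name, w, gene_ids, colnames(doc_term), weighting = "count")
  attr(out, "zero_genes") <- gene_ids[ndoc == 0]
  out
}

#' Zero-document genes flagged during aggregation
#' @param view A view produced by [aggregate_gene_profiles()].
#' @return Character vector of gene ids with no mapped documents.
#' @export
zero_genes <- function(view) attr(view, "zero_genes") %||% character(0)

#' Inverse-document-frequency weighting
#'
#' Rescales each term column of a count view by `idf(t) = log(D / df_t)`,
#' where `D` is the number of documents in the indexing matrix and `df_t`
#' the number of documents containing term `t`. Terms occurring in no
#' document get weight zero. Document frequency is computed on the
#' doc-by-term matrix of the same vocabulary by default; pass a merged
#' matrix to use corpus-wide frequencies instead.
#'
#' @param view Count-weighted [view()].
#' @param doc_term The document-by-term matrix the view was aggregated from.
#' @return An IDF-weighted view; `zero_genes` flags are carried over.
#' @export
idf_transform <- function(view, doc_term) {
  stopifnot(inherits(view, "mvtm_view"))
  if (view$weighting != "count") {
    stop("IDF weighting applies to count views.", call. = FALSE)
  }
  if (ncol(doc_term) != length(view$term_ids) ||
      !identical(colnames(doc_term), view$term_ids)) {
    stop("doc_term columns do not match the view's term space.", call. = FALSE)
  }
  D <- nrow(doc_term)
  df <- Matrix::colSums(doc_term > 0)
  idf <- ifelse(df > 0, log(D / df), 0)
  w <- view$weights %*% Matrix::Diagonal(x = idf)
  out <- view(view$name, w, view$gene_ids, view$term_ids, weighting = "idf")
  attr(out, "zero_genes") <- attr(view, "zero_genes")
  attr(out, "idf") <- idf
  out
}

#' Merge several vocabularies into one union view
#'
#' Indexes the corpus with the de-duplicated union of all term strings and
#' aggregates gene profiles, emulating the merged-vocabulary baseline in
#' which all controlled vocabularies are pooled before indexing.
#'
#' @param vocabs List of at least two [vocabulary()] objects.
#' @param corpus A [corpus()].
#' @param gene_doc_map Optional map; defaults to the corpus's own.
#' @param idf Apply IDF weighting (default `TRUE`).
#' @param name Name for the merged view.
#' @return A [view()] over the union vocabulary.
#' @export
merge_views <- function(vocabs, corpus, gene_doc_map = corpus$gene_doc_map,
                        idf = TRUE, name = "merged") {
  if (length(vocabs) < 2) stop("Need at least two vocabularies to merge.",
                               call. = FALSE)
  terms <- unique(unlist(lapply(vocabs, function(v) v$terms),
                         use.names = FALSE))
  voc <- vocabulary(name, terms)
  dt <- index_corpus(corpus, voc)
  v <- aggregate_gene_profiles(dt, gene_doc_map, name = name)
  if (idf) idf_transform(v, dt) else v
}

#' No-vocabulary baseline
#'
#' The baseline that indexes on every distinct token appearing in the
#' corpus, i.e. a vocabulary equal to the corpus token set.
#'
#' @param corpus A [corpus()].
#' @param name Vocabulary name.
#' @return A [vocabulary()] containing every corpus token.
#' @export
no_voc_vocabulary <- function(corpus, name = "no-voc") {
  toks <- sort(unique(unlist(lapply(corpus$documents, names),
                             use.names = FALSE)))
  vocabulary(name, toks)
}

#' Map synonym terms onto unified concepts
#'
#' Sums the columns of terms sharing a concept id into a single concept
#' column (concept mapping precedes IDF weighting). Terms absent from the
#' synonym table keep their own singleton concept. Each gene's total count
#' is conserved.
#'
#' @param view Count-weighted [view()].
#' @param synonyms Named character vector mapping term -> concept id.
#' @return A count-weighted gene-by-concept [view()].
#' @export
map_concepts <- function(view, synonyms) {
  stopifnot(inherits(view, "mvtm_view"))
  if (view$weighting != "count") {
    stop("Concept mapping precedes IDF weighting; pass a count view.",
         call. = FALSE)
  }
  concept <- ifelse(view$term_ids %in% names(synonyms),
                    unname(synonyms[view$term_ids]), view$term_ids)
  uc <- unique(concept)
  # terms-by-concepts summing operator
  S <- Matrix::sparseMatrix(
    i = seq_along(concept), j = match(concept, uc), x = 1,
    dims = c(length(concept), length(uc))
  )
  w <- view$weights %*% S
  out <- view(view$name, w, view$gene_ids, uc, weighting = "count")
  attr(out, "zero_genes") <- attr(view, "zero_genes")
  out
}
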