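#' Generate a synthetic multi-view disease-gene benchmark
#'
#' Emulates the data pipeline behind literature-based gene prioritization:
#' a corpus of documents about genes, indexed with several overlapping
#' controlled vocabularies of differing disease-relevance, aggregated to
#' gene-by-term profiles, together with a multi-disease labeled gene
#' benchmark containing a small fraction of multi-label genes.
#'
#' Each disease (and each "distractor" topic carried by unlabeled candidate
#' genes) is a latent term-topic: a subset of a per-view signature term pool.
#' A document about a gene mixes the gene's topic terms with background
#' terms; the per-view mixing weight is the view's `relevance`, so
#' `relevance = 1` gives a fully disease-informative view and
#' `relevance = 0` a pure-noise view. Document length is Poisson per view
#' block. Vocabularies are drawn from shared term pools sized so that two
#' views share roughly `overlap_frac` of their terms.
#'
#' @param n_diseases Number of diseases (>= 2).
#' @param genes_per_disease Integer vector (recycled) of genes per disease.
#' @param n_views Number of views/vocabularies.
#' @param relevance Per-view relevance in `[0, 1]` (recycled).
#' @param overlap_frac Approximate pairwise term overlap between
#'   vocabularies, in `[0, 1]`.
#' @param vocab_sizes Integer vector (recycled) of vocabulary sizes.
#' @param n_unlabeled Unlabeled genes forming the candidate pool.
#' @param multilabel_frac Fraction of labeled genes given a second disease.
#' @param docs_per_gene Mean number of documents per gene (at least one).
#' @param doc_length Mean tokens per document per view block.
#' @param sig_frac Fraction of each vocabulary devoted to signature terms.
#' @param topic_frac Fraction of the signature pool in each topic's signature.
#' @param weighting `"idf"` (profile weighting used throughout the package)
#'   or `"count"` for raw averaged counts.
#' @param seed Integer seed; the output is a pure function of the
#'   configuration and this seed.
#' @return A list of class `mvtm_benchmark` with elements `dataset`
#'   (a [multiview_dataset()]), `corpus`, `vocabularies`, `doc_terms`
#'   (per-view indexing matrices), and `config`.
#' @export
generate_benchmark <- function(n_diseases,
                               genes_per_disease,
                               n_views,
                               relevance,
                               overlap_frac = 0.2,
                               vocab_sizes = 100,
                               n_unlabeled = 300,
                               multilabel_frac = 0.05,
                               docs_per_gene = 3,
                               doc_length = 50,
                               sig_frac = 0.5,
                               topic_frac = 0.25,
                               weighting = c("idf", "count"),
                               seed = 1) {
  weighting <- match.arg(weighting)
  if (n_diseases < 2) stop("Need at least two diseases.", call. = FALSE)
  if (overlap_frac < 0 || overlap_frac > 1) {
    stop("`overlap_frac` must lie in [0, 1].", call. = FALSE)
  }
  relevance <- rep_len(relevance, n_views)
  if (any(relevance < 0 | relevance > 1)) {
    stop("`relevance` values must lie in [0, 1].", call. = FALSE)
  }
  genes_per_disease <- rep_len(as.integer(genes_per_disease), n_diseases)
  vocab_sizes <- rep_len(as.integer(vocab_sizes), n_views)
  if (any(genes_per_disease < 1) || any(vocab_sizes < 4)) {
    stop("Gene counts must be positive and vocabularies non-trivial.",
         call. = FALSE)
  }

  with_seed(seed, {
    diseases <- sprintf("d%02d", seq_len(n_diseases))
    n_extra <- max(n_diseases, 20)   # distractor/interest topic pool
    topics <- c(diseases, sprintf("x%02d", seq_len(n_extra)))

    # --- shared term pools sized for the requested vocabulary overlap ----
    pool_scale <- if (overlap_frac <= 0) Inf else 1 / overlap_frac
    sig_need <- ceiling(max(vocab_sizes) * sig_frac)
    bg_need <- max(vocab_sizes)
    sig_pool_size <- if (is.finite(pool_scale)) {
      ceiling(sig_need * pool_scale)
    } else {
      sig_need * n_views
    }
    bg_pool_size <- if (is.finite(pool_scale)) {
      ceiling(bg_need * pool_scale)
    } else {
      bg_need * n_views
    }
    sig_pool <- sprintf("sig%05d", seq_len(sig_pool_size))
    bg_pool <- sprintf("bkg%05d", seq_len(bg_pool_size))

    vocabs <- vector("list", n_views)
    sig_terms <- vector("list", n_views)   # per view: signature term subset
    bg_terms <- vector("list", n_views)
    topic_terms <- vector("list", n_views) # per view: topic -> term vector
    for (v in seq_len(n_views)) {
      # the share of signature terms scales with the view's relevance, so an
      # irrelevant vocabulary contains no disease-informative terms at all
      n_sig <- min(round(vocab_sizes[v] * sig_frac * relevance[v]),
                   sig_pool_size)
      n_bg <- min(vocab_sizes[v] - n_sig, bg_pool_size)
      if (is.finite(pool_scale)) {
        sv <- sample(sig_pool, n_sig)
        bv <- sample(bg_pool, n_bg)
      } else {                            # disjoint blocks per view
        sv <- sig_pool[(v - 1) * sig_need + seq_len(n_sig)]
        bv <- bg_pool[(v - 1) * bg_need + seq_len(n_bg)]
      }
      sig_terms[[v]] <- sv
      bg_terms[[v]] <- bv
      vocabs[[v]] <- vocabulary(sprintf("view%02d", v), c(sv, bv))
      k_topic <- max(3, ceiling(length(sv) * topic_frac))
      topic_terms[[v]] <- lapply(stats::setNames(topics, topics),
                                 function(t) sample(sv, min(k_topic, length(sv))))
    }

    # --- genes and labels -----------------------------------------------
    n_labeled <- sum(genes_per_disease)
    gene_ids <- sprintf("g%04d", seq_len(n_labeled + n_unlabeled))
    labeled <- gene_ids[seq_len(n_labeled)]
    unlabeled <- setdiff(gene_ids, labeled)
    labels <- stats::setNames(
      as.list(rep(diseases, genes_per_disease)), labeled
    )
    n_multi <- floor(multilabel_frac * n_labeled)
    if (n_multi > 0) {
      multi <- sample(labeled, n_multi)
      for (g in multi) {
        labels[[g]] <- c(labels[[g]],
                         sample(setdiff(diseases, labels[[g]]), 1))
      }
    }
    # every gene's literature mixes its disease topic(s) with one private
    # "interest" topic, so candidate genes can outrank a held-out disease
    # gene the way random human genes with their own literature can
    extra <- topics[-seq_len(n_diseases)]
    gene_topics <- c(
      lapply(labels, function(l) c(l, sample(extra, 1))),
      stats::setNames(lapply(unlabeled, function(g) sample(extra, 2)),
                      unlabeled)
    )

    # --- documents -------------------------------------------------------
    n_docs_per_gene <- 1L + stats::rpois(length(gene_ids),
                                         max(docs_per_gene - 1, 0))
    doc_gene <- rep(gene_ids, n_docs_per_gene)
    doc_ids <- sprintf("doc%05d", seq_along(doc_gene))
    gene_doc_map <- split(doc_ids, factor(doc_gene, levels = gene_ids))

    documents <- vector("list", length(doc_ids))
    names(documents) <- doc_ids
    disease_weight <- 0.7    # disease share of a labeled gene's topic tokens
    for (i in seq_along(doc_ids)) {
      tset <- gene_topics[[doc_gene[i]]]
      dis <- intersect(tset, diseases)
      per <- setdiff(tset, diseases)
      toks <- character(0)
      for (v in seq_len(n_views)) {
        L <- stats::rpois(1, doc_length)
        if (L == 0) next
        dis_terms <- unique(unlist(topic_terms[[v]][dis], use.names = FALSE))
        per_terms <- unique(unlist(topic_terms[[v]][per], use.names = FALSE))
        n_topic <- if (length(dis_terms) || length(per_terms)) {
          stats::rbinom(1, L, relevance[v])
        } else {
          0L
        }
        n_dis <- if (length(dis_terms) && length(per_terms)) {
          stats::rbinom(1, n_topic, disease_weight)
        } else if (length(dis_terms)) {
          n_topic
        } else {
          0L
        }
        if (n_dis > 0) {
          toks <- c(toks, sample(dis_terms, n_dis, replace = TRUE))
        }
        if (n_topic - n_dis > 0) {
          toks <- c(toks, sample(per_terms, n_topic - n_dis, replace = TRUE))
        }
        if (L - n_topic > 0) {
          toks <- c(toks, sample(bg_terms[[v]], L - n_topic, replace = TRUE))
        }
      }
      tab <- table(toks)
      documents[[i]] <- stats::setNames(as.integer(tab), names(tab))
    }
    corp <- corpus(documents, gene_doc_map)

    # --- views -----------------------------------------------------------
    doc_terms <- lapply(vocabs, function(voc) index_corpus(corp, voc))
    views <- vector("list", n_views)
    for (v in seq_len(n_views)) {
      cv <- aggregate_gene_profiles(doc_terms[[v]], gene_doc_map,
                                    name = vocabs[[v]]$name)
      views[[v]] <- if (weighting == "idf") {
        idf_transform(cv, doc_terms[[v]])
      } else {
        cv
      }
    }
    structure(
      list(
        dataset = multiview_dataset(views, labels),
        corpus = corp,
        vocabularies = vocabs,
        doc_terms = stats::setNames(doc_terms,
                                    vapply(vocabs, `[[`, "", "name")),
        config = list(
          n_diseases = n_diseases, genes_per_disease = genes_per_disease,
          n_views = n_views, relevance = relevance,
          overlap_frac = overlap_frac, vocab_sizes = vocab_sizes,
          n_unlabeled = n_unlabeled, multilabel_frac = multilabel_frac,
          docs_per_gene = docs_per_gene, doc_length = doc_length,
          sig_frac = sig_frac, topic_frac = topic_frac,
          weighting = weighting, seed = seed
        )
      ),
      class = "mvtm_benchmark"
    )
  })
}

#' @export
print.mvtm_benchmark <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic benchmark: ", cfg$n_diseases, " diseases, ",
      length(x$dataset$gene_ids), " genes, ", cfg$n_views,
      " views (relevance ", paste(signif(cfg$relevance, 2), collapse = "/"),
      "), seed ", cfg$seed, ">\n", sep = "")
  invisible(x)
}
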