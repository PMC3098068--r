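test_that("indexing counts vocabulary terms and ignores the rest", {
  corp <- tiny_corpus()
  voc <- vocabulary("v", c("muscle", "heart"))
  dt <- index_corpus(corp, voc)
  expect_equal(dim(dt), c(3L, 2L))
  expect_equal(as.numeric(dt["docA", ]), c(3, 0))
  expect_equal(as.numeric(dt["docB", ]), c(1, 2))

  disjoint <- vocabulary("w", c("lung", "kidney"))
  expect_equal(sum(index_corpus(corp, disjoint)), 0)

  # a term shared by two vocabularies indexes identically in both
  voc2 <- vocabulary("v2", c("muscle", "brain"))
  expect_equal(as.numeric(index_corpus(corp, voc)[, "muscle"]),
               as.numeric(index_corpus(corp, voc2)[, "muscle"]))
})

test_that("gene profiles are document means and zero-document genes are flagged", {
  corp <- tiny_corpus()
  dt <- index_corpus(corp, vocabulary("v", c("muscle", "heart")))
  v <- aggregate_gene_profiles(dt, corp$gene_doc_map)
  m <- as.matrix(v$weights)
  expect_equal(unname(m["g1", ]), c(3, 0))            # single document
  expect_equal(unname(m["g2", ]), c(0.5, 2))          # mean of two documents
  expect_equal(unname(m["g3", ]), c(0, 0))            # no documents
  expect_equal(zero_genes(v), "g3")

  expect_error(
    aggregate_gene_profiles(dt, list(g1 = "nope")),
    "without indexed rows"
  )
})

test_that("IDF downweights ubiquitous terms with idf = log(D/df)", {
  corp <- tiny_corpus()
  # heart is in 2 of 3 docs, muscle in 2 of 3; add a vocabulary with a
  # term in every document and a singleton term
  docs <- list(d1 = c(a = 1L, b = 1L), d2 = c(a = 2L), d3 = c(a = 1L, c = 1L))
  corp2 <- corpus(docs, list(g1 = c("d1", "d2", "d3")))
  dt <- index_corpus(corp2, vocabulary("v", c("a", "b", "zz")))
  v <- aggregate_gene_profiles(dt, corp2$gene_doc_map)
  vi <- idf_transform(v, dt)
  m <- as.matrix(vi$weights)
  expect_equal(unname(m[1, "a"]), 0)                  # df = D -> idf 0
  expect_equal(unname(m[1, "b"]), (1 / 3) * log(3))   # df = 1 of 3
  expect_equal(unname(m[1, "zz"]), 0)                 # df = 0 -> weight 0
  expect_equal(attr(vi, "idf")[["b"]], log(3))

  expect_error(idf_transform(vi, dt), "count views")
  dt_bad <- dt[, 1:2]
  expect_error(idf_transform(v, dt_bad), "term space")
})

test_that("idf magnitude matches the stated formula", {
  # D = 10 documents, one containing the term -> idf = ln(10)
  docs <- c(list(d1 = c(rare = 1L, common = 1L)),
            stats::setNames(replicate(9, c(common = 1L), simplify = FALSE),
                            paste0("d", 2:10)))
  corp <- corpus(docs, list(g = names(docs)))
  dt <- index_corpus(corp, vocabulary("v", c("rare", "common")))
  vi <- idf_transform(aggregate_gene_profiles(dt, corp$gene_doc_map), dt)
  expect_equal(attr(vi, "idf")[["rare"]], log(10), tolerance = 1e-12)
})

test_that("merging vocabularies unions terms and reproduces single views", {
  corp <- tiny_corpus()
  va <- vocabulary("a", c("muscle", "heart"))
  vb <- vocabulary("b", c("zzz", "lung"))
  merged <- merge_views(list(va, vb), corp, idf = FALSE)
  expect_equal(length(merged$term_ids), 4L)           # disjoint: sizes add

  # identical vocabularies merge to a view identical to either one
  same <- merge_views(list(va, va), corp, idf = FALSE)
  single <- aggregate_gene_profiles(index_corpus(corp, va),
                                    corp$gene_doc_map)
  expect_equal(as.matrix(same$weights[, single$term_ids]),
               as.matrix(single$weights))

  # overlap: union size strictly below the sum
  vc <- vocabulary("c", c("muscle", "lung"))
  expect_lt(length(merge_views(list(va, vc), corp, idf = FALSE)$term_ids), 4)
  expect_error(merge_views(list(va), corp), "at least two")
})

test_that("concept mapping sums synonym columns and conserves counts", {
  corp <- tiny_corpus()
  dt <- index_corpus(corp, vocabulary("v", c("muscle", "heart", "zzz")))
  v <- aggregate_gene_profiles(dt, corp$gene_doc_map)
  mapped <- map_concepts(v, c(muscle = "c1", heart = "c1"))
  m <- as.matrix(mapped$weights)
  expect_equal(unname(m["g2", "c1"]), 2.5)            # 0.5 + 2 summed
  expect_true("zzz" %in% mapped$term_ids)             # unmapped keeps itself
  # per-gene total conservation
  expect_equal(rowSums(m), rowSums(as.matrix(v$weights)))

  ident <- map_concepts(v, stats::setNames(v$term_ids, v$term_ids))
  expect_equal(as.matrix(ident$weights), as.matrix(v$weights))
})

test_that("indexing and aggregation commute with gene-order permutation", {
  withr::with_seed(7, {
    b <- small_benchmark(seed = 5, relevance = c(0.8, 0.3))
    corp <- b$corpus
    voc <- b$vocabularies[[1]]
    dt <- index_corpus(corp, voc)
    perm <- sample(names(corp$gene_doc_map))
    v1 <- aggregate_gene_profiles(dt, corp$gene_doc_map)
    v2 <- aggregate_gene_profiles(dt, corp$gene_doc_map[perm])
    expect_equal(as.matrix(v2$weights),
                 as.matrix(v1$weights)[perm, , drop = FALSE])
  })
})

test_that("no-voc baseline indexes every corpus token", {
  corp <- tiny_corpus()
  voc <- no_voc_vocabulary(corp)
  expect_setequal(voc$terms, c("muscle", "zzz", "heart"))
})

test_that("type constructors validate their invariants", {
  expect_error(vocabulary("v", character(0)), "non-empty")
  expect_error(vocabulary("v", c("a", "a")), "unique")
  expect_error(corpus(list(d1 = c(a = 1L)), list(g = "dX")), "unknown")
  expect_error(view("v", matrix(1, 2, 2), "g1", c("t1", "t2")),
               "dimensions")
  expect_error(view("v", matrix(-1, 1, 1), "g1", "t1", "count"),
               "non-negative")
  b <- small_benchmark(seed = 2, relevance = c(0.5, 0.5))
  vws <- b$dataset$views
  vws[[2]]$gene_ids <- rev(vws[[2]]$gene_ids)
  expect_error(multiview_dataset(vws, b$dataset$labels), "gene ordering")
})
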