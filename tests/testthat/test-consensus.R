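make_partition <- function(labels, ids = sprintf("g%02d", seq_along(labels))) {
  partition(stats::setNames(as.integer(labels), ids))
}

test_that("the co-association matrix accumulates pairwise votes", {
  p1 <- make_partition(c(1, 1, 2, 2))
  p2 <- make_partition(c(1, 2, 2, 1))
  p3 <- make_partition(c(1, 1, 1, 2))
  p4 <- make_partition(c(2, 2, 1, 1))
  s <- coassociation(list(p1, p2, p3, p4))
  expect_equal(unname(diag(unclass(s))), rep(1, 4))
  expect_equal(s[1, 2], 3 / 4)
  expect_equal(s[1, 3], 1 / 4)
  expect_true(isSymmetric(unclass(s)))
  # identical partitions give 0/1 entries
  s_same <- coassociation(list(p1, p1, p1))
  expect_true(all(unclass(s_same) %in% c(0, 1)))
})

test_that("every consensus method reproduces a unanimous ensemble", {
  truth <- c(rep(1, 6), rep(2, 6), rep(3, 6))
  parts <- lapply(1:4, function(i) make_partition(truth,
                                                  sprintf("g%02d", 1:18)))
  for (m in c("CSPA", "HGPA", "MCLA", "QMI", "EACAL", "AdacVote")) {
    p <- consensus_combine(parts, k = 3, method = m, seed = 2)
    expect_equal(agreement(p, make_partition(truth, sprintf("g%02d", 1:18)))$ri,
                 1, info = m)
  }
})

test_that("consensus is invariant to relabeling the input partitions", {
  withr::with_seed(5, {
    base <- lapply(1:5, function(i) {
      make_partition(sample(1:3, 15, replace = TRUE), sprintf("g%02d", 1:15))
    })
    relabeled <- lapply(base, function(p) {
      perm <- sample(3)
      make_partition(perm[p$labels], sprintf("g%02d", 1:15))
    })
    for (m in c("CSPA", "HGPA", "MCLA", "QMI", "EACAL", "AdacVote")) {
      p1 <- consensus_combine(base, k = 3, method = m, seed = 9)
      p2 <- consensus_combine(relabeled, k = 3, method = m, seed = 9)
      expect_equal(agreement(p1, p2)$ri, 1, info = m)
    }
  })
})

test_that("evidence accumulation recovers exact co-association blocks", {
  # 6 genes, two clean blocks across three partitions
  parts <- list(make_partition(c(1, 1, 1, 2, 2, 2)),
                make_partition(c(2, 2, 2, 1, 1, 1)),
                make_partition(c(1, 1, 1, 2, 2, 2)))
  s <- coassociation(parts)
  expect_equal(unname(unclass(s)[1:3, 1:3]), matrix(1, 3, 3))
  expect_equal(unname(unclass(s)[1:3, 4:6]), matrix(0, 3, 3))
  p <- consensus_combine(parts, k = 2, method = "EACAL", seed = 1)
  expect_equal(agreement(p, make_partition(c(1, 1, 1, 2, 2, 2)))$ri, 1)
})

test_that("consensus over noisy multi-view ensembles beats the median view", {
  gains <- logical(20)
  for (s in 1:20) {
    b <- generate_benchmark(2, 15, 9, relevance = c(rep(0.9, 5), rep(0, 4)),
                            vocab_sizes = 40, n_unlabeled = 10,
                            seed = 700 + s)
    genes <- names(b$dataset$labels)
    truth <- make_partition(
      ifelse(vapply(b$dataset$labels, function(l) "d01" %in% l, TRUE), 1, 2),
      genes)
    parts <- lapply(b$dataset$views, function(v) {
      kmeans_partition(as.matrix(v$weights)[genes, ], 2, seed = s)
    })
    ris <- vapply(parts, function(p) agreement(p, truth)$ri, numeric(1))
    cons <- consensus_combine(unname(parts), k = 2, method = "EACAL",
                              seed = s)
    gains[s] <- agreement(cons, truth)$ri >= stats::median(ris)
  }
  expect_gte(mean(gains), 0.9)
})

test_that("degenerate and invalid ensembles are rejected", {
  singletons <- lapply(1:2, function(i) make_partition(1:6))
  expect_error(consensus_combine(singletons, k = 2, method = "EACAL"),
               "singleton")
  p <- make_partition(c(1, 1, 2, 2))
  expect_error(consensus_combine(list(p, p), k = 2, method = "nope"))
  expect_error(consensus_combine(list(p), k = 2, method = "EACAL"),
               "at least two")
  q <- make_partition(c(1, 2), c("a", "b"))
  expect_error(consensus_combine(list(p, q), k = 2, method = "EACAL"),
               "different gene sets")
})
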