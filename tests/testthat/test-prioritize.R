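test_that("the disease model is the training-set mean profile", {
  x <- rbind(g1 = c(1, 0), g2 = c(0, 1))
  expect_equal(build_model(x), c(0.5, 0.5))
  expect_equal(build_model(x[1, , drop = FALSE]), c(1, 0))
  expect_equal(build_model(x[2:1, ]), build_model(x))
  expect_error(build_model(matrix(0, 2, 3)), "all-zero")
})

test_that("correlation scoring follows the Pearson conventions", {
  model <- c(1, 2, 3, 4)
  cand <- rbind(same = model, anti = -model + 5, flat = rep(2, 4))
  s <- score_correlation(model, cand)
  expect_equal(unname(s["same"]), 1)
  expect_equal(unname(s["anti"]), -1)
  expect_equal(unname(s["flat"]), 0)
  expect_error(score_correlation(model, cand[, 1:3]), "dimension")
  # zero-variance model scores everything 0
  expect_equal(unname(score_correlation(rep(1, 4), cand)), rep(0, 3))
})

test_that("ranking orders by score with deterministic id tie-breaks", {
  r <- rank_candidates(c(b = 0.1, a = 0.9))
  expect_equal(r$candidate_id, c("a", "b"))
  expect_equal(r$rank_ratio, c(0.5, 1))

  tied <- rank_candidates(c(z = 0.5, a = 0.5, m = 0.5))
  expect_equal(tied$candidate_id, c("a", "m", "z"))

  many <- rank_candidates(stats::setNames(seq_len(100) / 100,
                                          sprintf("g%03d", 100:1)))
  expect_equal(many$rank_ratio[1], 0.01)
  expect_equal(many$candidate_id[1], "g001")
})

test_that("score fusion is the element-wise mean or maximum", {
  a <- c(g1 = 1, g2 = 0)
  b <- c(g2 = 1, g1 = 0)
  expect_equal(fuse_scores(list(a, b), "average"), c(g1 = 0.5, g2 = 0.5))
  expect_equal(fuse_scores(list(a, b), "max"), c(g1 = 1, g2 = 1))
  expect_equal(fuse_scores(list(a, a), "average"), a)
  expect_equal(fuse_scores(list(a, a), "max"), a)
  expect_error(fuse_scores(list(a), "max"), "at least two")
  expect_error(fuse_scores(list(a, c(g1 = 1, g3 = 2))), "different candidate")
})

test_that("leave-one-out error has the right extremes and null level", {
  b <- small_benchmark(seed = 6, relevance = c(1, 0.9), n_diseases = 3,
                       genes = 8, unlabeled = 60)
  # a fully informative view ranks most defectors near the top
  r <- loo_benchmark(b$dataset, "single-view", n_candidates = 50,
                     n_reps = 1, seed = 3)
  best <- min(r$summary$mean_error)
  expect_lt(best, 0.2)

  # random scores give error about one half
  withr::with_seed(12, {
    errs <- replicate(1000, {
      sc <- rnorm(100)
      1 - (sum(sc[1] > sc[-1]) + 0.5 * sum(sc[1] == sc[-1])) / 99
    })
    expect_equal(mean(errs), 0.5, tolerance = 0.02)
  })
})

test_that("leave-one-out is reproducible and validates its pool", {
  b <- small_benchmark(seed = 8, relevance = c(0.35, 0.25), n_diseases = 3,
                       genes = 6, unlabeled = 60)
  r1 <- loo_benchmark(b$dataset, "average", n_candidates = 30, n_reps = 2,
                      seed = 5)
  r2 <- loo_benchmark(b$dataset, "average", n_candidates = 30, n_reps = 2,
                      seed = 5)
  expect_identical(r1$detail, r2$detail)
  r3 <- loo_benchmark(b$dataset, "average", n_candidates = 30, n_reps = 2,
                      seed = 6)
  expect_false(identical(r1$detail$error, r3$detail$error))

  expect_error(loo_benchmark(b$dataset, "average", n_candidates = 1000),
               "pool")
})

test_that("integration methods agree with direct per-task computation", {
  b <- small_benchmark(seed = 14, relevance = c(0.9, 0.7, 0.4),
                       n_diseases = 2, genes = 5, unlabeled = 40)
  ds <- b$dataset
  r <- loo_benchmark(ds, "order-statistics", n_candidates = 20, n_reps = 1,
                     seed = 9)
  expect_true(all(r$detail$error >= 0 & r$detail$error <= 1))
  # order statistics with all views agreeing perfectly puts Q at its minimum
  ratios <- matrix(1 / 21, 1, 3)
  expect_lt(q_statistic_rows(ratios)[1], q_statistic_rows(matrix(0.5, 1, 3))[1])
})
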