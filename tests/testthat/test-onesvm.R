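# Shared seeded fixture: three views of one gene set, one informative.
onesvm_fixture <- function(seed = 13, n = 60, n_train = 12) {
  withr::with_seed(seed, {
    ids <- sprintf("g%03d", seq_len(n))
    signal <- c(rep(1, n_train), rep(0, n - n_train))
    x1 <- cbind(signal * 2 + rnorm(n, 0, 0.4), matrix(rnorm(n * 4), n, 4))
    x2 <- cbind(signal * 1.5 + rnorm(n, 0, 0.6), matrix(rnorm(n * 4), n, 4))
    x3 <- matrix(rnorm(n * 5), n, 5)
    rownames(x1) <- rownames(x2) <- rownames(x3) <- ids
    list(kernels = lapply(list(x1, x2, x3), kernel_matrix),
         train = ids[seq_len(n_train)], ids = ids)
  })
}

test_that("the inner one-class QP agrees with the kernlab ipop oracle", {
  skip_if_not_installed("kernlab")
  withr::with_seed(31, {
    for (i in 1:5) {
      m <- sample(5:25, 1)
      a <- matrix(rnorm(m * m), m)
      h <- crossprod(a) / m + diag(m) * 0.01
      ub <- 1 / (0.5 * m)
      mine <- solve_box_simplex_qp(h, ub)
      or <- kernlab::ipop(
        c = rep(0, m), H = 2 * h, A = matrix(1, 1, m), b = 1, r = 0,
        l = rep(0, m), u = rep(ub, m)
      )
      alpha_or <- kernlab::primal(or)
      val_or <- drop(crossprod(alpha_or, h %*% alpha_or))
      expect_equal(mine$value, val_or, tolerance = 1e-4)
    }
  })
})

test_that("fusion weights and dual variables satisfy the program constraints", {
  fx <- onesvm_fixture()
  for (mm in c(0, 0.5 / 3, 1 / 3)) {
    fit <- fit_one_svm_fusion(fx$kernels, fx$train, nu = 0.5, mu_min = mm)
    expect_equal(sum(fit$mu), 1, tolerance = 1e-6)
    expect_true(all(fit$mu >= mm - 1e-9))
    expect_true(all(fit$alphas >= -1e-9))
    expect_true(all(fit$alphas <= 1 / (0.5 * length(fx$train)) + 1e-9))
    expect_equal(sum(fit$alphas), 1, tolerance = 1e-8)
  }
  # mu_min = 1/N reproduces the uniform combination exactly
  fit_u <- fit_one_svm_fusion(fx$kernels, fx$train, mu_min = 1 / 3)
  expect_identical(fit_u$mu, rep(1 / 3, 3))
})

test_that("identical kernels collapse to the single-kernel optimum", {
  fx <- onesvm_fixture()
  k <- fx$kernels[[1]]
  same <- list(k, k, k)
  fit3 <- fit_one_svm_fusion(same, fx$train, mu_min = 0)
  fit1 <- fit_one_svm_fusion(list(k), fx$train, mu_min = 1)
  expect_equal(fit3$t_value, fit1$t_value, tolerance = 1e-6)
})

test_that("relaxing the weight bound cannot shrink the attained margin objective", {
  fx <- onesvm_fixture()
  t0 <- fit_one_svm_fusion(fx$kernels, fx$train, mu_min = 0)$t_value
  tu <- fit_one_svm_fusion(fx$kernels, fx$train, mu_min = 1 / 3)$t_value
  expect_gte(t0, tu - 1e-8)
})

test_that("scores are bounded and favour genes resembling the training set", {
  fx <- onesvm_fixture()
  fit <- fit_one_svm_fusion(fx$kernels, fx$train, mu_min = 1 / 3)
  s <- score_one_svm(fit, fx$ids)
  expect_true(all(s >= -1 & s <= 1))
  # across seeds, training-like genes outscore background genes
  wins <- 0
  for (seed in 1:20) {
    fs <- onesvm_fixture(seed = 200 + seed)
    ft <- fit_one_svm_fusion(fs$kernels, fs$train, mu_min = 1 / 3,
                             check = FALSE)
    sc <- score_one_svm(ft, fs$ids)
    trained <- mean(sc[fs$train])
    other <- mean(sc[setdiff(fs$ids, fs$train)])
    wins <- wins + (trained > other)
  }
  expect_gte(wins, 18)
  expect_error(score_one_svm(fit, "nope"), "Unknown candidate")
})

test_that("a degenerate weight vector reproduces single-kernel scoring", {
  fx <- onesvm_fixture()
  fit_fix <- fit_one_svm_fusion(fx$kernels, fx$train, mu = c(1, 0, 0))
  fit_one <- fit_one_svm_fusion(fx$kernels[1], fx$train, mu_min = 1)
  s1 <- score_one_svm(fit_fix, fx$ids)
  s2 <- score_one_svm(fit_one, fx$ids)
  # trace normalization differs by a constant factor; rankings must agree
  expect_equal(cor(s1, s2), 1, tolerance = 1e-6)
})

test_that("invalid inputs are rejected", {
  fx <- onesvm_fixture()
  expect_error(fit_one_svm_fusion(fx$kernels, fx$train[1]), "two training")
  expect_error(fit_one_svm_fusion(fx$kernels, fx$train, nu = 0), "nu")
  expect_error(fit_one_svm_fusion(fx$kernels, fx$train, mu_min = 0.9),
               "mu_min")
  bad <- fx$kernels
  bad[[1]]$gram[1, 2] <- bad[[1]]$gram[1, 2] + 5   # break symmetry/PSD
  bad[[1]]$gram[2, 1] <- bad[[1]]$gram[2, 1] + 5
  expect_error(fit_one_svm_fusion(bad, fx$train, check = TRUE),
               "positive semidefinite")
})
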