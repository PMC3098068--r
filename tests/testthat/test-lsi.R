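test_that("decomposition recovers known spectra", {
  u <- c(1, 2, 3, 4) / sqrt(30)
  v <- c(2, 1, 2) / 3
  x <- outer(u, v)
  rownames(x) <- paste0("g", 1:4)
  vw <- view("r1", x, rownames(x), paste0("t", 1:3), weighting = "latent")
  dec <- suppressWarnings(lsi_decompose(vw, max_rank = 2))
  expect_equal(dec$singular_values[1], 1, tolerance = 1e-10)
  expect_lt(dec$singular_values[2], 1e-10)

  # orthogonal columns scaled (3, 2, 1) give those singular values
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:3]
  x2 <- q %*% diag(c(3, 2, 1))
  x2 <- t(x2)                                 # 3 genes x 5 terms
  rownames(x2) <- paste0("g", 1:3)
  vw2 <- view("r2", x2, rownames(x2), paste0("t", 1:5), weighting = "latent")
  dec2 <- suppressWarnings(lsi_decompose(vw2, max_rank = 2,
                                         threshold_fraction = 0.05))
  expect_equal(dec2$singular_values, c(3, 2), tolerance = 1e-10)
})

test_that("sparse-view spectrum matches a dense Gram-eigenvalue oracle", {
  withr::with_seed(11, {
    x <- matrix(0, 50, 200)
    nz <- sample(length(x), 800)
    x[nz] <- rnorm(800)
    rownames(x) <- sprintf("g%02d", 1:50)
    vw <- view("s", x, rownames(x), sprintf("t%03d", 1:200),
               weighting = "latent")
    dec <- suppressWarnings(lsi_decompose(vw, max_rank = 20))
    # oracle: eigenvalues of the dense Gram matrix
    ev <- eigen(tcrossprod(x), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(dec$singular_values, sqrt(pmax(ev[1:20], 0)),
                 tolerance = 1e-8)
  })
  expect_error(lsi_decompose(vw <- view("t", matrix(1, 3, 3),
                                        paste0("g", 1:3), paste0("t", 1:3),
                                        weighting = "latent"),
                             max_rank = 5), "max_rank")
})

test_that("the spectrum-fraction rule selects the documented rank", {
  expect_equal(select_rank(c(100, 0.01), 5e-4), 1L)
  expect_warning(k <- select_rank(c(1, 1, 1, 1), 5e-4), "threshold")
  expect_equal(k, 4L)
  expect_equal(select_rank(c(10, 5, 1, 0.004), 5e-4), 3L)
  expect_error(select_rank(c(0, 0)), "not all zero")
  expect_error(select_rank(c(1, 2, 3)), "non-increasing")
})

test_that("select_rank is monotone in the threshold fraction", {
  withr::with_seed(3, {
    for (i in 1:20) {
      vals <- sort(rexp(30, 1), decreasing = TRUE)
      ks <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1),
                   function(f) suppressWarnings(select_rank(vals, f)),
                   integer(1))
      expect_true(all(diff(ks) <= 0))
    }
  })
})

test_that("full-rank projection preserves gene geometry", {
  withr::with_seed(5, {
    x <- matrix(rnorm(15 * 40), 15, 40)
    rownames(x) <- paste0("g", 1:15)
    x[3, ] <- x[1, ]                            # duplicate gene rows
    vw <- view("p", x, rownames(x), paste0("t", 1:40), weighting = "latent")
    dec <- suppressWarnings(lsi_decompose(vw, max_rank = 14))
    z <- lsi_project(vw, dec, k = 14)
    zm <- as.matrix(z$weights)
    expect_equal(as.matrix(dist(zm)), as.matrix(dist(x)), tolerance = 1e-8)
    expect_equal(tcrossprod(zm), tcrossprod(x), tolerance = 1e-8)
    expect_equal(unname(zm[1, ]), unname(zm[3, ]), tolerance = 1e-10)
  })
})

test_that("latent projection keeps planted topics separable", {
  # planted two-topic gene-by-term matrix: each gene's counts follow one of
  # two sparse topic distributions over 50 terms plus term noise
  ri_term <- numeric(20)
  ri_lat <- numeric(20)
  for (s in 1:20) {
    withr::with_seed(400 + s, {
      topics <- rbind(c(rep(4, 15), rep(0.2, 35)),
                      c(rep(0.2, 35), rep(4, 15)))
      lab <- rep(1:2, each = 20)
      x <- t(vapply(lab, function(l) {
        as.numeric(stats::rmultinom(1, 60, topics[l, ]))
      }, numeric(50)))
      rownames(x) <- sprintf("g%02d", 1:40)
      vw <- view("planted", x, rownames(x), sprintf("t%02d", 1:50))
      truth <- partition(stats::setNames(lab, rownames(x)))
      dec <- suppressWarnings(lsi_decompose(vw, max_rank = 10))
      z <- lsi_project(vw, dec, k = 2)
      pt <- kmeans_partition(x, 2, seed = s)
      pl <- kmeans_partition(as.matrix(z$weights), 2, seed = s)
      ri_term[s] <- agreement(pt, truth)$ri
      ri_lat[s] <- agreement(pl, truth)$ri
    })
  }
  expect_gte(mean(ri_lat), mean(ri_term) - 0.05)
})

test_that("projection rejects a mismatched term space", {
  x <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
  vw <- view("a", x, rownames(x), paste0("t", 1:5), weighting = "latent")
  dec <- suppressWarnings(lsi_decompose(vw, max_rank = 2,
                                        threshold_fraction = 0.05))
  other <- view("b", x, rownames(x), paste0("u", 1:5), weighting = "latent")
  expect_error(lsi_project(other, dec), "term space")
})
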