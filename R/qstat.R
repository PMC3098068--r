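# Vectorized Q recursion over rows of a matrix of ascending-sorted ratios.
# V_0 = 1; V_k = sum_{i=1..k} (-1)^(i-1) V_{k-i} r_{N-k+1}^i / i!;  Q = N! V_N.
q_recursion <- function(r_sorted) {
  n_obs <- nrow(r_sorted)
  n <- ncol(r_sorted)
  v <- matrix(0, n_obs, n + 1)
  v[, 1] <- 1
  for (k in seq_len(n)) {
    rk <- r_sorted[, n - k + 1]
    acc <- 0
    for (i in seq_len(k)) {
      acc <- acc + (-1)^(i - 1) * v[, k - i + 1] * rk^i / factorial(i)
    }
    v[, k + 1] <- acc
  }
  list(q = pmin(pmax(factorial(n) * v[, n + 1], 0), 1), v = v)
}

#' Q statistic of N rank ratios
#'
#' The joint cumulative probability that the order statistics of `N`
#' independent uniform variables all fall below the observed sorted rank
#' ratios. A small Q means a gene is ranked consistently high across data
#' sources. Computed with the fast `V_k` recursion rather than the
#' N-dimensional integral.
#'
#' @param ratios Numeric vector of rank ratios in `(0, 1]` (sorted
#'   internally, so the result does not depend on view order).
#' @return An object of class `mvtm_qstat` with fields `value`, `n_sources`,
#'   `ratios`, and `v_coeffs` (`V_0 ... V_N`).
#' @export
q_statistic <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (length(ratios) < 1 || any(ratios <= 0 | ratios > 1)) {
    stop("Rank ratios must lie in (0, 1].", call. = FALSE)
  }
  r <- sort(ratios)
  res <- q_recursion(matrix(r, nrow = 1))
  structure(list(value = res$q[1], n_sources = length(r),
                 ratios = r, v_coeffs = drop(res$v)),
            class = "mvtm_qstat")
}

#' @export
print.mvtm_qstat <- function(x, ...) {
  cat("<Q statistic: Q = ", signif(x$value, 5), " from ", x$n_sources,
      " rank ratios>\n", sep = "")
  invisible(x)
}

#' Q values for every row of a rank-ratio matrix
#'
#' Vectorized form of [q_statistic()] over a genes-by-views matrix of rank
#' ratios, as used when combining the per-view rankings of a whole
#' candidate set.
#'
#' @param ratio_matrix Numeric matrix of rank ratios in `(0, 1]`, one row
#'   per gene, one column per view.
#' @return Numeric vector of Q values, one per row.
#' @export
q_statistic_rows <- function(ratio_matrix) {
  if (any(ratio_matrix <= 0 | ratio_matrix > 1)) {
    stop("Rank ratios must lie in (0, 1].", call. = FALSE)
  }
  sorted <- t(apply(ratio_matrix, 1, sort))
  if (ncol(ratio_matrix) == 1) sorted <- matrix(sorted, ncol = 1)
  q_recursion(sorted)$q
}

#' Calibrate the null distribution of the Q statistic
#'
#' Draws Q values under independent uniform rank ratios and fits the null
#' by maximum likelihood: a beta distribution when the number of sources is
#' at most five, a gamma distribution otherwise.
#'
#' @param n_sources Number of data sources N.
#' @param n_samples Monte-Carlo sample size (at least 10^4).
#' @param seed Integer seed.
#' @return An object of class `mvtm_qcal` with fields `n_sources`, `family`
#'   (`"beta"` or `"gamma"`), `params`, `n_samples`, `seed`.
#' @export
calibrate_q <- function(n_sources, n_samples = 10000, seed = 1) {
  if (n_samples < 10000) {
    stop("Calibration needs at least 10^4 samples.", call. = FALSE)
  }
  q <- with_seed(seed, {
    r <- matrix(runif(n_samples * n_sources), n_samples, n_sources)
    q_statistic_rows(r)
  })
  family <- if (n_sources <= 5) "beta" else "gamma"
  fit <- tryCatch({
    if (family == "beta") {
      x <- pmin(pmax(q, 1e-10), 1 - 1e-10)
      m <- mean(x); v <- var(x)
      c0 <- max(m * (1 - m) / v - 1, 1e-3)
      MASS::fitdistr(x, "beta",
                     start = list(shape1 = m * c0, shape2 = (1 - m) * c0),
                     lower = c(1e-6, 1e-6))
    } else {
      x <- pmax(q, 1e-12)
      m <- mean(x); v <- var(x)
      MASS::fitdistr(x, "gamma",
                     start = list(shape = m^2 / v, rate = m / v),
                     lower = c(1e-8, 1e-8))
    }
  }, error = function(e) {
    stop("Q calibration failed for N = ", n_sources, ": ",
         conditionMessage(e), " (sample mean ", signif(mean(q), 4),
         ", sd ", signif(stats::sd(q), 4), ")", call. = FALSE)
  })
  structure(list(n_sources = n_sources, family = family,
                 params = fit$estimate, n_samples = n_samples, seed = seed),
            class = "mvtm_qcal")
}

#' @export
print.mvtm_qcal <- function(x, ...) {
  cat("<Q calibration: N = ", x$n_sources, ", ", x$family, "(",
      paste(signif(x$params, 4), collapse = ", "), "), ",
      x$n_samples, " samples>\n", sep = "")
  invisible(x)
}

#' P-value of a Q statistic under the calibrated null
#'
#' Left-tail probability of the observed Q under the fitted beta or gamma
#' null; genes are then ranked by ascending p-value.
#'
#' @param q An [q_statistic()] result, or a numeric vector of Q values.
#' @param cal A [calibrate_q()] result with matching number of sources.
#' @return Numeric p-value(s) in `[0, 1]`.
#' @export
q_pvalue <- function(q, cal) {
  stopifnot(inherits(cal, "mvtm_qcal"))
  if (inherits(q, "mvtm_qstat")) {
    if (q$n_sources != cal$n_sources) {
      stop("Calibration was fitted for N = ", cal$n_sources,
           ", not N = ", q$n_sources, ".", call. = FALSE)
    }
    q <- q$value
  }
  if (cal$family == "beta") {
    pbeta(q, cal$params[["shape1"]], cal$params[["shape2"]])
  } else {
    pgamma(q, cal$params[["shape"]], cal$params[["rate"]])
  }
}
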