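#' @importFrom stats rpois runif rnorm sd cor kmeans hclust cutree as.dist
#'   dist pbeta pgamma qbeta qgamma t.test var
#' @importFrom utils head read.delim write.table
#' @importFrom rlang .data
NULL

# Derive a stream of child seeds from a master seed; keeps values in the
# 32-bit signed range R requires.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.numeric(seed) * 48271 + 7919 * seq_len(n)) %% 2147483629
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483629))
  force(code)
}

#' Project a vector onto the simplex with a common lower bound
#'
#' Finds the Euclidean projection of `v` onto
#' `{x : sum(x) = 1, x_i >= lower}`. Used to keep kernel combination
#' weights feasible.
#'
#' @param v Numeric vector.
#' @param lower Common lower bound, in `[0, 1/length(v)]`.
#' @return Numeric vector of the same length summing to one.
#' @keywords internal
project_simplex <- function(v, lower = 0) {
  n <- length(v)
  if (lower < 0 || lower > 1 / n + 1e-12) {
    stop("`lower` must lie in [0, 1/N].", call. = FALSE)
  }
  if (abs(lower - 1 / n) < 1e-12) {
    return(rep(1 / n, n))
  }
  # shift so the residual mass projects onto the standard simplex
  w <- v - lower
  mass <- 1 - n * lower
  u <- sort(w, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - mass) / seq_len(n) > 0))
  theta <- (css[rho] - mass) / rho
  pmax(w - theta, 0) + lower
}

# Projection onto {0 <= x <= ub, sum(x) = 1}: exact breakpoint scan of the
# piecewise-linear shift equation sum(clip(v - theta, 0, ub)) = 1.
project_box_simplex <- function(v, ub) {
  n <- length(v)
  if (n * ub < 1 - 1e-12) {
    stop("Box-constrained simplex is empty: upper bounds sum below one.",
         call. = FALSE)
  }
  bp <- sort(c(v, v - ub))
  fv <- colSums(pmin(pmax(outer(v, bp, "-"), 0), ub))
  j <- findInterval(-1, -fv)        # last index with fv >= 1 (fv decreasing)
  theta <- if (j == 0) {
    bp[1]                            # ub * n == 1 exactly: saturate all
  } else if (j >= length(bp) || fv[j] == fv[j + 1]) {
    bp[j]
  } else {
    bp[j] + (fv[j] - 1) * (bp[j + 1] - bp[j]) / (fv[j] - fv[j + 1])
  }
  pmin(pmax(v - theta, 0), ub)
}

# Midranks of x in descending order (largest score -> rank 1).
midrank_desc <- function(x) {
  rank(-x, ties.method = "average")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
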