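#' Optimized kernel K-means clustering (OKKC)
#'
#' Alternates two steps until the partition stabilizes: (i) Girolami-style
#' kernel K-means on the current convex combination of trace-normalized
#' kernels, and (ii) a kernel-fusion step that re-weights the kernels to
#' maximize the between-cluster separation of the current labels,
#' `s_i = sum_j u_j' (K_i / r_i) u_j` (with `u_j` the normalized cluster
#' indicators and `r_i` the kernel trace), smoothed by a ridge `lambda` on
#' the weights. Both steps descend one objective — the fused within-cluster
#' distortion plus `lambda * ||mu||^2` — so the recorded objective trace is
#' monotone non-increasing. The weight update is the closed-form solution
#' of its quadratic program: the projection of `s / (2 lambda)` onto the
#' simplex bounded below by `mu_min`. Small `lambda` therefore yields
#' near-vertex (sparse) weights, large `lambda` near-uniform ones.
#'
#' With `mu_min = 1/N` the weights are pinned uniform and the fusion step
#' is skipped: the algorithm is exactly kernel K-means on the averaged
#' (trace-normalized) kernel with the same seed.
#'
#' @param kernels List of aligned, centered PSD `mvtm_kernel` objects.
#' @param k Number of clusters (>= 2).
#' @param lambda Weight-smoothing regularization (> 0), default `0.01`.
#' @param mu_min Lower bound on each kernel weight, in `[0, 1/N]`.
#' @param seed Integer seed for the kernel K-means initialization.
#' @param max_iter Maximum alternations, default 50.
#' @param n_restarts Restarts for the initial kernel K-means.
#' @return A list with `partition` (an [partition()]) and `state` (class
#'   `mvtm_okkc`: `mu`, `mu_min`, `betas`, `lambda`, `labels`, `k`,
#'   `objective_trace`, `iterations`).
#' @export
okkc <- function(kernels, k, lambda = 0.01, mu_min = 0, seed = 1,
                 max_iter = 50, n_restarts = 10) {
  ids <- check_aligned_kernels(kernels)
  n_k <- length(kernels)
  n <- length(ids)
  if (k < 2) stop("OKKC requires k >= 2.", call. = FALSE)
  if (lambda <= 0) stop("`lambda` must be positive.", call. = FALSE)
  if (mu_min < 0 || mu_min > 1 / n_k + 1e-12) {
    stop("`mu_min` must lie in [0, 1/N].", call. = FALSE)
  }
  g_hat <- lapply(kernels, function(kk) kk$gram / kk$trace_r)
  combine <- function(mu) Reduce(`+`, Map(`*`, g_hat, mu))

  separation <- function(labels) {
    z <- indicator_matrix(labels, k)
    sizes <- pmax(colSums(z), 1)
    u <- sweep(z, 2, sqrt(sizes), "/")
    vapply(g_hat, function(g) sum(u * (g %*% u)), numeric(1))
  }
  objective <- function(labels, mu) {
    1 - sum(separation(labels) * mu) + lambda * sum(mu^2)
  }

  uniform <- abs(mu_min - 1 / n_k) < 1e-12
  mu <- rep(1 / n_k, n_k)
  part <- kernel_kmeans(combine(mu), k, seed = seed, n_restarts = n_restarts)
  labels <- partition_labels(part)
  trace <- objective(labels, mu)
  iters <- 0L

  if (!uniform) {
    for (it in seq_len(max_iter)) {
      iters <- it
      mu_new <- project_simplex(separation(labels) / (2 * lambda),
                                lower = mu_min)
      part_new <- kernel_kmeans(combine(mu_new), k, init_labels = labels)
      labels_new <- partition_labels(part_new)
      obj <- objective(labels_new, mu_new)
      trace <- c(trace, obj)
      converged <- identical(labels_new, labels)
      mu <- mu_new
      labels <- labels_new
      if (converged) break
    }
  }

  kc <- combine(mu)
  betas <- vapply(seq_len(k), function(j) {
    l_j <- ifelse(labels == j, 1, -1)
    solve(kc + lambda * diag(n), l_j)
  }, numeric(n))

  state <- structure(
    list(mu = mu, mu_min = mu_min, betas = betas, lambda = lambda,
         labels = labels, k = k, objective_trace = trace,
         iterations = iters),
    class = "mvtm_okkc"
  )
  list(partition = partition(stats::setNames(labels, ids), k = k),
       state = state)
}

#' @export
print.mvtm_okkc <- function(x, ...) {
  cat("<OKKC: k = ", x$k, ", mu = (", paste(signif(x$mu, 3), collapse = ", "),
      "), ", x$iterations, " iteration(s), objective ",
      signif(utils::tail(x$objective_trace, 1), 5), ">\n", sep = "")
  invisible(x)
}
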