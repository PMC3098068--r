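#' Solve the one-class SVM dual QP
#'
#' Minimizes `alpha' H alpha` over the nu-one-class polytope
#' `{sum(alpha) = 1, 0 <= alpha_i <= ub}` by accelerated projected
#' gradient with an exact projection onto the box-constrained simplex.
#' `H` must be symmetric positive semidefinite.
#'
#' @param h Symmetric PSD matrix.
#' @param ub Common upper bound on the dual variables (`1/(nu M)`).
#' @param tol Stopping tolerance on the iterate change.
#' @param max_iter Iteration cap.
#' @return List with `alpha` and the attained `value`.
#' @export
solve_box_simplex_qp <- function(h, ub, tol = 1e-9, max_iter = 2000) {
  m <- nrow(h)
  lip <- 2 * max(abs(eigen(h, symmetric = TRUE, only.values = TRUE)$values))
  if (lip <= 0) lip <- 1
  step <- 1 / lip
  alpha <- project_box_simplex(rep(1 / m, m), ub)
  y <- alpha
  tk <- 1
  for (it in seq_len(max_iter)) {
    grad <- 2 * (h %*% y)
    alpha_new <- project_box_simplex(y - step * drop(grad), ub)
    delta <- max(abs(alpha_new - alpha))
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- alpha_new + ((tk - 1) / tk_new) * (alpha_new - alpha)
    alpha <- alpha_new
    tk <- tk_new
    if (delta < tol) break
    if (it %% 50 == 0) { tk <- 1; y <- alpha }  # momentum restart
  }
  list(alpha = drop(alpha), value = drop(crossprod(alpha, h %*% alpha)))
}

#' One-class SVM fusion of view kernels
#'
#' Learns a convex combination of centered linear kernels that maximizes the
#' one-class margin of the disease training genes: the quadratically
#' constrained program `min t` subject to
#' `alpha' G_j alpha / r_j <= t` for every kernel, with
#' `0 <= alpha_i <= 1/(nu M)` and `sum(alpha) = 1`, where `G_j` is the
#' training submatrix of the j-th kernel and `r_j` its trace scale. The
#' kernel weights `mu` are the duals of the quadratic constraints; a lower
#' bound `mu_min` on each weight interpolates between the sparse optimum
#' (`mu_min = 0`) and the uniform kernel average (`mu_min = 1/N`). The
#' program is solved through its saddle-point form: the concave function
#' `h(mu) = min_alpha alpha' K(mu) alpha` is maximized over the bounded
#' weight simplex by projected supergradient ascent, with the inner
#' one-class QP solved by accelerated projected gradient.
#'
#' @param kernels List of aligned, centered `mvtm_kernel` objects over
#'   training plus candidate genes.
#' @param training_ids At least two gene ids present in the kernels.
#' @param nu One-class regularization in `(0, 1]`; the fraction of training
#'   genes allowed to act as outliers. Default `0.5`.
#' @param mu_min Lower bound on each kernel weight, in `[0, 1/N]`.
#' @param mu Optional fixed weight vector (bypasses the weight
#'   optimization); must be non-negative and sum to one.
#' @param outer_iter Supergradient ascent iterations for the weight search.
#' @param check Validate PSD-ness of the training submatrices (disable in
#'   tight loops where kernels are PSD by construction).
#' @return An object of class `mvtm_onesvm` with fields `alphas`, `mu`,
#'   `mu_min`, `nu`, `training_ids`, `t_value`, and `combined_kernel`
#'   (the mu-weighted, trace-normalized Gram over all genes).
#' @export
fit_one_svm_fusion <- function(kernels, training_ids, nu = 0.5, mu_min = 0,
                               mu = NULL, outer_iter = 60, check = TRUE) {
  ids <- check_aligned_kernels(kernels)
  n_k <- length(kernels)
  if (!all(training_ids %in% ids)) {
    stop("Training genes missing from the kernels.", call. = FALSE)
  }
  m <- length(training_ids)
  if (m < 2) stop("Need at least two training genes.", call. = FALSE)
  if (nu <= 0 || nu > 1) stop("`nu` must lie in (0, 1].", call. = FALSE)
  if (mu_min < 0 || mu_min > 1 / n_k + 1e-12) {
    stop("`mu_min` must lie in [0, 1/N].", call. = FALSE)
  }
  ub <- 1 / (nu * m)
  g_hat <- lapply(kernels, function(k) {
    g <- k$gram[training_ids, training_ids, drop = FALSE] / k$trace_r
    if (check) {
      ev <- min(eigen(g, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-8 * max(1, max(abs(g)))) {
        stop("Kernel is not positive semidefinite (min eigenvalue ",
             signif(ev, 3), ").", call. = FALSE)
      }
    }
    g
  })
  combine_g <- function(w) Reduce(`+`, Map(`*`, g_hat, w))

  if (!is.null(mu)) {
    if (length(mu) != n_k || any(mu < -1e-12) || abs(sum(mu) - 1) > 1e-6) {
      stop("Fixed `mu` must be a convex combination over the kernels.",
           call. = FALSE)
    }
    mu <- pmax(mu, 0); mu <- mu / sum(mu)
    sol <- solve_box_simplex_qp(combine_g(mu), ub)
    alpha <- sol$alpha; t_val <- sol$value
  } else if (abs(mu_min - 1 / n_k) < 1e-12) {
    mu <- rep(1 / n_k, n_k)
    sol <- solve_box_simplex_qp(combine_g(mu), ub)
    alpha <- sol$alpha; t_val <- sol$value
  } else {
    mu <- rep(1 / n_k, n_k)
    best <- list(h = -Inf, mu = mu, alpha = NULL)
    for (it in seq_len(outer_iter)) {
      sol <- solve_box_simplex_qp(combine_g(mu), ub)
      if (sol$value > best$h) {
        best <- list(h = sol$value, mu = mu, alpha = sol$alpha)
      }
      grad <- vapply(g_hat, function(g) {
        drop(crossprod(sol$alpha, g %*% sol$alpha))
      }, numeric(1))
      step <- 0.5 / (max(abs(grad)) + 1e-12) / sqrt(it)
      mu <- project_simplex(mu + step * grad, lower = mu_min)
    }
    mu <- best$mu
    alpha <- best$alpha %||% solve_box_simplex_qp(combine_g(mu), ub)$alpha
    t_val <- best$h
  }

  names(alpha) <- training_ids
  structure(
    list(alphas = alpha, mu = mu, mu_min = mu_min, nu = nu,
         training_ids = training_ids, t_value = t_val,
         combined_kernel = combine_kernels(kernels, mu = mu,
                                           trace_normalize = TRUE)),
    class = "mvtm_onesvm"
  )
}

#' @export
print.mvtm_onesvm <- function(x, ...) {
  cat("<one-class SVM fusion: ", length(x$mu), " kernels, ",
      length(x$training_ids), " training genes, nu = ", x$nu,
      ", mu = (", paste(signif(x$mu, 3), collapse = ", "),
      "), t = ", signif(x$t_value, 5), ">\n", sep = "")
  invisible(x)
}

#' Score candidate genes with a fitted fusion model
#'
#' `score(x) = sum_i alpha_i Omega(x, x_i)` under the combined kernel
#' `Omega`, normalized by the model norm `sqrt(alpha' Omega alpha)` and the
#' candidate's self-similarity `sqrt(Omega(x, x))` so scores lie in
#' `[-1, +1]`; larger scores mean stronger similarity to the disease model.
#' Candidates with (numerically) zero self-similarity score 0.
#'
#' @param model A [fit_one_svm_fusion()] result.
#' @param candidate_ids Gene ids present in the fitted kernels.
#' @return Named numeric scores in `[-1, 1]`.
#' @export
score_one_svm <- function(model, candidate_ids) {
  stopifnot(inherits(model, "mvtm_onesvm"))
  omega <- model$combined_kernel$gram
  miss <- setdiff(candidate_ids, rownames(omega))
  if (length(miss) > 0) {
    stop("Unknown candidate genes: ", paste(head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  a <- model$alphas
  tr_ids <- model$training_ids
  raw <- drop(omega[candidate_ids, tr_ids, drop = FALSE] %*% a)
  model_norm <- sqrt(max(drop(crossprod(a, omega[tr_ids, tr_ids] %*% a)), 0))
  self <- pmax(diag(omega)[candidate_ids], 0)
  denom <- model_norm * sqrt(self)
  s <- ifelse(denom > 1e-12, raw / pmax(denom, 1e-300), 0)
  stats::setNames(pmin(pmax(s, -1), 1), candidate_ids)
}
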