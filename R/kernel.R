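#' Centered linear kernel of a view
#'
#' Builds the Gram matrix used by all kernel-fusion methods: gene rows are
#' normalized to unit Euclidean norm (zero rows stay zero), the linear Gram
#' matrix is formed, and the features are mean-centered, which makes the
#' Gram matrix double-centered while remaining positive semidefinite by
#' construction. Only linear kernels are used because gene-by-term profiles
#' are high-dimensional.
#'
#' @param view A [view()] or a numeric matrix with gene rownames.
#' @param center Mean-center the (normalized) features; default `TRUE`.
#' @return An object of class `mvtm_kernel` with fields `gram` (symmetric
#'   PSD matrix), `centered`, `trace_r` (the trace, used as the kernel's
#'   regularization scale in fusion), and `gene_ids`.
#' @export
kernel_matrix <- function(view, center = TRUE) {
  x <- if (inherits(view, "mvtm_view")) view_matrix(view) else as.matrix(view)
  gene_ids <- rownames(x) %||% sprintf("g%04d", seq_len(nrow(x)))
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x <- x / nrm
  if (center) x <- sweep(x, 2, colMeans(x))
  k <- tcrossprod(x)
  k <- (k + t(k)) / 2
  dimnames(k) <- list(gene_ids, gene_ids)
  structure(list(gram = k, centered = center,
                 trace_r = sum(diag(k)), gene_ids = gene_ids),
            class = "mvtm_kernel")
}

#' @export
print.mvtm_kernel <- function(x, ...) {
  cat("<kernel: ", length(x$gene_ids), " genes, trace ",
      signif(x$trace_r, 4), if (x$centered) ", centered", ">\n", sep = "")
  invisible(x)
}

#' Restrict a kernel to a subset of genes
#'
#' Takes the submatrix of the Gram matrix; the trace scale is recomputed on
#' the submatrix. Pairwise feature-space distances (and hence kernel
#' K-means and Hilbert-space linkage) are unchanged by where the centering
#' was performed.
#'
#' @param kernel An `mvtm_kernel`.
#' @param ids Gene ids to keep.
#' @return An `mvtm_kernel` over `ids`.
#' @export
kernel_subset <- function(kernel, ids) {
  miss <- setdiff(ids, kernel$gene_ids)
  if (length(miss) > 0) {
    stop("Genes absent from kernel: ", paste(head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  g <- kernel$gram[ids, ids, drop = FALSE]
  structure(list(gram = g, centered = kernel$centered,
                 trace_r = sum(diag(g)), gene_ids = ids),
            class = "mvtm_kernel")
}

check_aligned_kernels <- function(kernels) {
  stopifnot(length(kernels) >= 1)
  ids <- kernels[[1]]$gene_ids
  for (k in kernels) {
    if (!inherits(k, "mvtm_kernel") || !identical(k$gene_ids, ids)) {
      stop("Kernels must be `mvtm_kernel` objects over one gene ordering.",
           call. = FALSE)
    }
  }
  ids
}

#' Convex combination of kernels
#'
#' @param kernels List of aligned `mvtm_kernel` objects.
#' @param mu Weights (default uniform); must be non-negative.
#' @param trace_normalize Divide each kernel by its trace before combining
#'   (the scaling used inside the fusion optimizers).
#' @return An `mvtm_kernel`.
#' @export
combine_kernels <- function(kernels, mu = NULL, trace_normalize = FALSE) {
  ids <- check_aligned_kernels(kernels)
  n <- length(kernels)
  mu <- mu %||% rep(1 / n, n)
  if (length(mu) != n || any(mu < -1e-12)) {
    stop("`mu` must be a non-negative weight per kernel.", call. = FALSE)
  }
  g <- matrix(0, length(ids), length(ids))
  for (j in seq_len(n)) {
    scale_j <- if (trace_normalize) kernels[[j]]$trace_r else 1
    g <- g + mu[j] * kernels[[j]]$gram / scale_j
  }
  dimnames(g) <- list(ids, ids)
  structure(list(gram = g, centered = all(vapply(kernels, `[[`, TRUE, "centered")),
                 trace_r = sum(diag(g)), gene_ids = ids),
            class = "mvtm_kernel")
}

#' Distance matrix in the fused Hilbert space
#'
#' Averages (or `mu`-weights) the view kernels and converts the combined
#' kernel into feature-space distances,
#' `d(x, z) = sqrt(K(x,x) - 2 K(x,z) + K(z,z))`. With unit-norm rows and
#' linear kernels this is the Euclidean distance between the concatenated
#' weighted features, so the subsequent linkage clustering is ordinary
#' hierarchical clustering in that space.
#'
#' @param kernels List of aligned `mvtm_kernel` objects.
#' @param mu Kernel weights; default uniform.
#' @return A symmetric non-negative distance matrix of class
#'   `mvtm_hilbert_dist` with zero diagonal.
#' @export
hilbert_distance <- function(kernels, mu = NULL) {
  k <- combine_kernels(kernels, mu = mu, trace_normalize = FALSE)
  dg <- diag(k$gram)
  d2 <- outer(dg, dg, "+") - 2 * k$gram
  low <- min(d2)
  if (low < -1e-8) {
    stop("Combined kernel produced a negative squared distance (",
         signif(low, 3), "); kernels are not jointly PSD.", call. = FALSE)
  }
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(d, class = c("mvtm_hilbert_dist", "matrix"))
}
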