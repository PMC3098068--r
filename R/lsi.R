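#' Latent semantic indexing of a gene-by-term view
#'
#' Computes the top singular triplets of the view's weight matrix. The
#' decomposition is fitted on the full gene universe of the view (labeled
#' and unlabeled genes alike), mirroring whole-collection fitting; at the
#' scale this package targets the truncated decomposition is taken from an
#' exact LAPACK singular value decomposition.
#'
#' @param view A [view()].
#' @param max_rank Number of factors to compute; must be at least 1 and at
#'   most `min(genes, terms) - 1`. Default `min(genes, terms, 500) - 1`.
#' @param threshold_fraction Spectrum fraction used later by
#'   [select_rank()]; stored with the decomposition. Default `0.0005`
#'   (0.05 percent).
#' @param use One of `"singular"` (apply the spectrum rule to singular
#'   values) or `"squared"` (to their squares, i.e. Gram eigenvalues).
#' @return An object of class `mvtm_lsi` with fields `singular_values`,
#'   `gene_factors`, `term_factors`, `k_selected`, `threshold_fraction`.
#' @export
lsi_decompose <- function(view, max_rank = NULL,
                          threshold_fraction = 0.0005,
                          use = c("singular", "squared")) {
  use <- match.arg(use)
  x <- view_matrix(view)
  r_max <- min(dim(x)) - 1L
  if (is.null(max_rank)) max_rank <- min(nrow(x), ncol(x), 500L) - 1L
  if (max_rank < 1 || max_rank > r_max) {
    stop("`max_rank` must lie in [1, min(genes, terms) - 1].", call. = FALSE)
  }
  sv <- svd(x, nu = max_rank, nv = max_rank)
  d <- sv$d[seq_len(max_rank)]
  vals <- if (use == "squared") d^2 else d
  k <- select_rank(vals, threshold_fraction)
  structure(
    list(singular_values = d,
         gene_factors = sv$u,
         term_factors = sv$v,
         k_selected = k,
         threshold_fraction = threshold_fraction,
         use = use,
         term_ids = view$term_ids,
         view_name = view$name),
    class = "mvtm_lsi"
  )
}

#' @export
print.mvtm_lsi <- function(x, ...) {
  cat("<LSI decomposition of '", x$view_name, "': ",
      length(x$singular_values), " factors computed, k = ", x$k_selected,
      " selected (fraction ", x$threshold_fraction, ")>\n", sep = "")
  invisible(x)
}

#' Choose the number of latent factors from a spectrum
#'
#' Returns the smallest `k` such that the `(k+1)`-th value falls below
#' `fraction` times the sum of all computed values. If no value falls below
#' the threshold, returns the number of computed values with a warning.
#'
#' @param values Non-increasing, non-negative spectrum (singular values or
#'   eigenvalues), not all zero.
#' @param fraction Threshold fraction; default `0.0005`.
#' @return Integer number of factors to keep.
#' @export
select_rank <- function(values, fraction = 0.0005) {
  if (length(values) == 0 || any(values < -1e-12) || all(values == 0)) {
    stop("Spectrum must be non-negative and not all zero.", call. = FALSE)
  }
  if (is.unsorted(rev(values))) {
    stop("Spectrum must be sorted non-increasing.", call. = FALSE)
  }
  thr <- fraction * sum(values)
  below <- which(values < thr)
  if (length(below) == 0) {
    warning("No value falls below the spectrum threshold; keeping all ",
            length(values), " factors.", call. = FALSE)
    return(length(values))
  }
  max(min(below) - 1L, 1L)
}

#' Project a view onto its latent factors
#'
#' Expresses gene rows in the selected latent basis: gene factors scaled by
#' the singular values. At full computed rank the projection preserves
#' pairwise gene inner products and Euclidean distances, so kernel- and
#' distance-based steps downstream are unchanged.
#'
#' @param view The [view()] the decomposition was computed from (term space
#'   must match).
#' @param dec An [lsi_decompose()] result.
#' @param k Number of factors; defaults to `dec$k_selected`.
#' @return A `"latent"`-weighted [view()] with `k` columns.
#' @export
lsi_project <- function(view, dec, k = dec$k_selected) {
  stopifnot(inherits(dec, "mvtm_lsi"))
  if (!identical(view$term_ids, dec$term_ids)) {
    stop("Decomposition was computed on a different term space.",
         call. = FALSE)
  }
  k <- min(k, length(dec$singular_values))
  z <- view_matrix(view) %*% dec$term_factors[, seq_len(k), drop = FALSE]
  out <- view(paste0(view$name, "-lsi"), z, view$gene_ids,
              paste0("f", seq_len(k)), weighting = "latent")
  attr(out, "zero_genes") <- attr(view, "zero_genes")
  out
}
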