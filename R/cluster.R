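#' Cluster partition
#'
#' @param labels Integer cluster ids in `1..k`, optionally named by gene.
#' @param k Number of clusters; defaults to `max(labels)`.
#' @return An object of class `mvtm_partition`.
#' @export
partition <- function(labels, k = max(labels)) {
  ids <- names(labels)
  labels <- stats::setNames(as.integer(labels), ids)
  if (any(is.na(labels)) || any(labels < 1) || any(labels > k)) {
    stop("Cluster labels must lie in 1..k for every gene.", call. = FALSE)
  }
  structure(list(labels = labels, k = as.integer(k),
                 gene_ids = names(labels)),
            class = "mvtm_partition")
}

#' @export
print.mvtm_partition <- function(x, ...) {
  cat("<partition: ", length(x$labels), " genes in ", x$k, " clusters (",
      paste(tabulate(x$labels, x$k), collapse = "/"), ")>\n", sep = "")
  invisible(x)
}

partition_labels <- function(p) {
  if (inherits(p, "mvtm_partition")) p$labels else as.integer(p)
}

indicator_matrix <- function(labels, k = max(labels)) {
  z <- matrix(0, length(labels), k)
  z[cbind(seq_along(labels), labels)] <- 1
  z
}

#' K-means partition of a view
#'
#' The base clustering algorithm: Euclidean K-means on gene rows, best of
#' `n_restarts` random starts by within-cluster sum of squares,
#' deterministic for a given seed.
#'
#' @param view A [view()] or numeric matrix of gene rows.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 10).
#' @return An [partition()] named by gene id.
#' @export
kmeans_partition <- function(view, k, seed = 1, n_restarts = 10) {
  x <- if (inherits(view, "mvtm_view")) view_matrix(view) else as.matrix(view)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop("k = ", k, " exceeds the ", n_distinct, " distinct gene rows.",
         call. = FALSE)
  }
  if (k == 1) {
    return(partition(stats::setNames(rep(1L, nrow(x)), rownames(x)), k = 1))
  }
  fit <- with_seed(seed, kmeans(x, centers = k, nstart = n_restarts,
                                iter.max = 50))
  partition(stats::setNames(as.integer(fit$cluster), rownames(x)), k = k)
}

# Girolami-style kernel K-means: assignments minimize feature-space
# distance to implicit centroids; emptied clusters are re-seeded at the
# point farthest from its centroid.
kernel_kmeans <- function(kernel, k, seed = 1, n_restarts = 10,
                          max_iter = 100, init_labels = NULL) {
  g <- if (inherits(kernel, "mvtm_kernel")) kernel$gram else as.matrix(kernel)
  n <- nrow(g)
  if (k > n) stop("k exceeds the number of genes.", call. = FALSE)
  dg <- diag(g)

  run_once <- function(labels) {
    for (iter in seq_len(max_iter)) {
      sizes <- tabulate(labels, k)
      while (any(sizes == 0)) {         # re-seed an emptied cluster
        z <- indicator_matrix(labels, k)
        zs <- sweep(z, 2, pmax(sizes, 1), "/")
        m <- g %*% zs
        s <- colSums(zs * m)
        d_self <- dg - 2 * m[cbind(seq_len(n), labels)] + s[labels]
        far <- which.max(d_self)
        labels[far] <- which(sizes == 0)[1]
        sizes <- tabulate(labels, k)
      }
      z <- indicator_matrix(labels, k)
      zs <- sweep(z, 2, sizes, "/")
      m <- g %*% zs                     # n x k cross terms
      s <- colSums(zs * m)              # per-cluster self terms
      d2 <- sweep(-2 * m, 2, s, "+") + dg
      new_labels <- max.col(-d2, ties.method = "first")
      if (identical(new_labels, labels)) break
      labels <- new_labels
    }
    sizes <- tabulate(labels, k)
    z <- indicator_matrix(labels, k)
    zs <- sweep(z, 2, pmax(sizes, 1), "/")
    m <- g %*% zs
    s <- colSums(zs * m)
    dist <- sum(dg - 2 * m[cbind(seq_len(n), labels)] + s[labels])
    list(labels = labels, distortion = dist)
  }

  if (!is.null(init_labels)) {
    best <- run_once(as.integer(init_labels))
  } else {
    seeds <- derive_seeds(seed, n_restarts)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- with_seed(seeds[r], {
        lab <- sample.int(k, n, replace = TRUE)
        lab[sample.int(n, k)] <- seq_len(k)   # every cluster starts occupied
        lab
      })
      res <- run_once(init)
      if (is.null(best) || res$distortion < best$distortion - 1e-12) {
        best <- res
      }
    }
  }
  ids <- if (inherits(kernel, "mvtm_kernel")) kernel$gene_ids else rownames(g)
  out <- partition(stats::setNames(best$labels, ids), k = k)
  attr(out, "distortion") <- best$distortion
  out
}

#' Agglomerative partition of a Hilbert-space distance matrix
#'
#' Builds the dendrogram with the requested linkage and cuts it to `k`
#' clusters. Ward linkage uses the squared-distance update
#' (`stats::hclust` method `"ward.D2"`), appropriate for the Euclidean
#' feature-space distances produced by [hilbert_distance()].
#'
#' @param dist A distance matrix (e.g. from [hilbert_distance()]).
#' @param method `"single"`, `"complete"`, `"average"`, or `"ward"`.
#' @param k Number of clusters.
#' @return An [partition()].
#' @export
linkage_partition <- function(dist, method = c("ward", "single", "complete",
                                               "average"), k = 2) {
  method <- match.arg(method)
  hc_method <- if (method == "ward") "ward.D2" else method
  d <- as.matrix(dist)
  hc <- hclust(as.dist(d), method = hc_method)
  labels <- cutree(hc, k = k)
  partition(stats::setNames(as.integer(labels),
                            rownames(d) %||% names(labels)), k = k)
}
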