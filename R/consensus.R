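check_aligned_partitions <- function(partitions) {
  if (length(partitions) < 1) stop("Need at least one partition.", call. = FALSE)
  n <- length(partition_labels(partitions[[1]]))
  ids <- partitions[[1]]$gene_ids
  for (p in partitions) {
    if (length(partition_labels(p)) != n ||
        !identical(p$gene_ids, ids)) {
      stop("Partitions cover different gene sets.", call. = FALSE)
    }
  }
  list(n = n, ids = ids)
}

#' Co-association matrix of a partition ensemble
#'
#' Entry `(i, j)` is the fraction of partitions placing genes `i` and `j`
#' in the same cluster — the accumulated "votes" on pairwise
#' co-occurrence.
#'
#' @param partitions List of aligned [partition()]s.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal, of class
#'   `mvtm_coassoc`.
#' @export
coassociation <- function(partitions) {
  meta <- check_aligned_partitions(partitions)
  s <- matrix(0, meta$n, meta$n)
  for (p in partitions) {
    z <- indicator_matrix(partition_labels(p), p$k)
    s <- s + tcrossprod(z)
  }
  s <- s / length(partitions)
  dimnames(s) <- list(meta$ids, meta$ids)
  structure(s, class = c("mvtm_coassoc", "matrix"))
}

# k-way spectral partition of a similarity matrix (replaces the METIS
# graph partitioner): normalized-Laplacian embedding + seeded k-means.
spectral_partition <- function(s, k, seed = 1, n_restarts = 10) {
  d <- rowSums(s)
  d[d <= 0] <- 1
  l <- s / sqrt(d) / rep(sqrt(d), each = nrow(s))
  ev <- eigen((l + t(l)) / 2, symmetric = TRUE)
  u <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(u^2))
  nrm[nrm == 0] <- 1
  u <- u / nrm
  fit <- with_seed(seed, kmeans(u, centers = k, nstart = n_restarts,
                                iter.max = 50))
  as.integer(fit$cluster)
}

# Relabel clusters by first appearance so every consensus step sees a
# canonical encoding; this makes all methods exactly invariant to how the
# input partitions happen to number their clusters.
canonical_labels <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

partition_entropy <- function(labels) {
  p <- tabulate(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Greedy label alignment of `labels` onto `ref` by descending overlap.
align_labels <- function(labels, ref, k_ref) {
  k_p <- max(labels)
  tab <- table(factor(ref, levels = seq_len(k_ref)),
               factor(labels, levels = seq_len(k_p)))
  map <- integer(k_p)
  tab_work <- tab
  for (step in seq_len(min(k_ref, k_p))) {
    idx <- which(tab_work == max(tab_work), arr.ind = TRUE)[1, ]
    map[idx[2]] <- idx[1]
    tab_work[idx[1], ] <- -1
    tab_work[, idx[2]] <- -1
  }
  for (j in which(map == 0)) map[j] <- which.max(tab[, j])
  map[labels]
}

#' Combine a partition ensemble with a consensus function
#'
#' Six consensus functions over aligned partitions of one gene set:
#' \describe{
#'   \item{CSPA}{k-way spectral partition of the co-association similarity
#'     graph.}
#'   \item{HGPA}{k-way cut of the cluster hypergraph (each cluster one
#'     hyperedge) via a bipartite spectral embedding of the
#'     gene-by-hyperedge incidence.}
#'   \item{MCLA}{hyperedges greedily merged into k meta-clusters by Jaccard
#'     similarity; genes assigned to the meta-cluster they participate in
#'     most.}
#'   \item{QMI}{K-means in the centered cluster-indicator feature space
#'     (the category-utility / quadratic-mutual-information criterion).}
#'   \item{EACAL}{average-linkage dendrogram on one minus the
#'     co-association matrix, cut to k (evidence accumulation).}
#'   \item{AdacVote}{cumulative voting against an adaptive reference, the
#'     partitions taken in decreasing order of entropy; each gene goes to
#'     its maximum-probability cluster.}
#' }
#' The spectral embeddings with seeded K-means replace the external
#' METIS/hMETIS partitioners used by the original graph-based algorithms.
#' All methods are invariant to relabeling of the input partitions.
#'
#' @param partitions List of at least two aligned [partition()]s.
#' @param k Number of consensus clusters (>= 2).
#' @param method One of `"CSPA"`, `"HGPA"`, `"MCLA"`, `"QMI"`, `"EACAL"`,
#'   `"AdacVote"`.
#' @param seed Integer seed for the seeded sub-steps.
#' @return An [partition()].
#' @export
consensus_combine <- function(partitions, k,
                              method = c("CSPA", "HGPA", "MCLA", "QMI",
                                         "EACAL", "AdacVote"),
                              seed = 1) {
  method <- match.arg(method)
  if (length(partitions) < 2) {
    stop("Consensus needs at least two partitions.", call. = FALSE)
  }
  if (k < 2) stop("Consensus requires k >= 2.", call. = FALSE)
  meta <- check_aligned_partitions(partitions)
  n <- meta$n
  partitions <- lapply(partitions, function(p) {
    partition(stats::setNames(canonical_labels(partition_labels(p)),
                              p$gene_ids), k = p$k)
  })
  label_mat <- vapply(partitions, partition_labels, integer(n))
  if (all(apply(label_mat, 2, function(l) length(unique(l))) == n)) {
    stop("Degenerate ensemble: every partition is all-singleton.",
         call. = FALSE)
  }

  labels <- switch(
    method,
    CSPA = {
      s <- unclass(coassociation(partitions))
      spectral_partition(s, k, seed = seed)
    },
    HGPA = {
      h <- do.call(cbind, lapply(partitions, function(p) {
        indicator_matrix(partition_labels(p), p$k)
      }))
      d1 <- pmax(rowSums(h), 1)
      d2 <- pmax(colSums(h), 1)
      an <- h / sqrt(d1) / rep(sqrt(d2), each = n)
      sv <- svd(an, nu = k, nv = 0)
      u <- sv$u
      nrm <- sqrt(rowSums(u^2)); nrm[nrm == 0] <- 1
      fit <- with_seed(seed, kmeans(u / nrm, centers = k, nstart = 10,
                                    iter.max = 50))
      as.integer(fit$cluster)
    },
    MCLA = {
      h <- do.call(cbind, lapply(partitions, function(p) {
        indicator_matrix(partition_labels(p), p$k)
      }))
      h <- h[, colSums(h) > 0, drop = FALSE]
      n_h <- ncol(h)
      groups <- as.list(seq_len(n_h))
      inter <- crossprod(h)
      sizes <- colSums(h)
      jac <- inter / (outer(sizes, sizes, "+") - inter)
      diag(jac) <- -Inf
      while (length(groups) > k) {
        # greedy best match: merge the two meta-clusters whose hyperedges
        # are most similar on average
        best <- c(1, 2); best_val <- -Inf
        for (i in seq_along(groups)) {
          for (j in seq_len(i - 1)) {
            v <- mean(jac[groups[[i]], groups[[j]]])
            if (v > best_val) { best_val <- v; best <- c(j, i) }
          }
        }
        groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
        groups[[best[2]]] <- NULL
      }
      assoc <- vapply(groups, function(g) {
        rowMeans(h[, g, drop = FALSE])
      }, numeric(n))
      max.col(assoc, ties.method = "first")
    },
    QMI = {
      f <- do.call(cbind, lapply(partitions, function(p) {
        z <- indicator_matrix(partition_labels(p), p$k)
        sweep(z, 2, colMeans(z))
      }))
      fit <- with_seed(seed, kmeans(f, centers = k, nstart = 10,
                                    iter.max = 50))
      as.integer(fit$cluster)
    },
    EACAL = {
      s <- unclass(coassociation(partitions))
      hc <- hclust(as.dist(1 - s), method = "average")
      as.integer(cutree(hc, k = k))
    },
    AdacVote = {
      ent <- apply(label_mat, 2, partition_entropy)
      ord <- order(-ent)
      ref_labels <- label_mat[, ord[1]]
      k_ref <- max(partitions[[ord[1]]]$k, k)
      v <- indicator_matrix(ref_labels, k_ref)
      count <- 1
      for (j in ord[-1]) {
        aligned <- align_labels(label_mat[, j], max.col(v, ties.method = "first"),
                                k_ref)
        v <- (count * v + indicator_matrix(aligned, k_ref)) / (count + 1)
        count <- count + 1
      }
      lab <- max.col(v, ties.method = "first")
      # compact empty reference clusters so labels stay in 1..k'
      as.integer(factor(lab))
    }
  )
  partition(stats::setNames(as.integer(labels), meta$ids),
            k = max(labels, k))
}
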