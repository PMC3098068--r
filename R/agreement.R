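#' Rand index and normalized mutual information of two partitions
#'
#' Counts the four types of gene pairs — `a` same cluster in both
#' partitions, `b` different in both, `c` same in the first and different
#' in the second, `d` different in the first and same in the second — and
#' reports the Rand index `RI = (a + b) / (a + b + c + d)` together with
#' the mutual information `M` between the label vectors and the NMI
#' normalized by the geometric mean of the two entropies. For a binary
#' problem, independent random partitions give RI around 0.5 and NMI
#' approaching 0.
#'
#' @param partition An [partition()] (or integer labels): the cluster
#'   indicators.
#' @param labels An [partition()] (or integer labels) of the same genes:
#'   the reference (disease) labels.
#' @return An object of class `mvtm_agreement` with fields `a`, `b`, `c`,
#'   `d`, `ri`, `mi`, `entropy_c`, `entropy_p`, `nmi`, `n`.
#' @export
agreement <- function(partition, labels) {
  c_lab <- partition_labels(partition)
  p_lab <- partition_labels(labels)
  if (length(c_lab) != length(p_lab)) {
    stop("Partitions cover different gene sets.", call. = FALSE)
  }
  if (inherits(partition, "mvtm_partition") &&
      inherits(labels, "mvtm_partition") &&
      !is.null(partition$gene_ids) && !is.null(labels$gene_ids) &&
      !identical(partition$gene_ids, labels$gene_ids)) {
    stop("Partitions cover different gene sets.", call. = FALSE)
  }
  n <- length(c_lab)
  tab <- table(c_lab, p_lab)
  total <- choose(n, 2)
  a <- sum(choose(tab, 2))
  same_c <- sum(choose(rowSums(tab), 2))
  same_p <- sum(choose(colSums(tab), 2))
  cc <- same_c - a
  dd <- same_p - a
  b <- total - a - cc - dd
  ri <- if (total > 0) (a + b) / total else 1

  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  e_c <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  e_p <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  nmi <- if (e_c > 0 && e_p > 0) {
    mi / sqrt(e_c * e_p)
  } else if (e_c == 0 && e_p == 0) {
    1   # both trivial single-cluster partitions agree completely
  } else {
    0
  }
  structure(list(a = a, b = b, c = cc, d = dd, ri = ri, mi = mi,
                 entropy_c = e_c, entropy_p = e_p,
                 nmi = min(max(nmi, 0), 1), n = n),
            class = "mvtm_agreement")
}

#' @export
print.mvtm_agreement <- function(x, ...) {
  cat("<agreement over ", x$n, " genes: RI = ", signif(x$ri, 4),
      ", NMI = ", signif(x$nmi, 4), " (a=", x$a, " b=", x$b, " c=", x$c,
      " d=", x$d, ")>\n", sep = "")
  invisible(x)
}

#' Enumerate disease pairs for the two-disease clustering protocol
#'
#' @param diseases Character vector of disease ids.
#' @return Tibble with columns `disease_a`, `disease_b`, one row per
#'   unordered pair (`choose(n, 2)` rows).
#' @export
disease_pairs <- function(diseases) {
  diseases <- sort(unique(diseases))
  idx <- utils::combn(length(diseases), 2)
  tibble::tibble(disease_a = diseases[idx[1, ]],
                 disease_b = diseases[idx[2, ]])
}

#' All-pairs two-disease clustering evaluation
#'
#' For every unordered pair of diseases: take the genes labeled with either
#' disease, remove genes labeled with both, cluster the remainder into two
#' groups with the requested method, and score the partition against the
#' disease labels with the Rand index and NMI. Results are averaged over
#' all pairs and repetitions; pairs left with fewer than four genes after
#' overlap removal are skipped with a warning.
#'
#' @param dataset A [multiview_dataset()].
#' @param method `"single-view"` (every view scored separately),
#'   `"consensus"` (per-view K-means combined by `consensus_method`),
#'   `"kernel-kmeans"` (averaged kernel), `"linkage"` (Hilbert-space
#'   linkage on the averaged kernel), or `"okkc"`.
#' @param n_reps Repetitions with fresh clustering seeds.
#' @param seed Integer seed.
#' @param consensus_method Consensus function for `method = "consensus"`.
#' @param linkage_method Linkage for `method = "linkage"` (default ward).
#' @param mu_min,lambda OKKC parameters.
#' @param n_restarts K-means restarts.
#' @param views Optional subset of view names.
#' @return An object of class `mvtm_cluster_eval`: list with `detail`
#'   (one row per pair x rep x reporting unit), `summary` (mean/sd of RI
#'   and NMI), `n_pairs`, and `config`.
#' @export
pairwise_disease_eval <- function(dataset,
                                  method = c("single-view", "consensus",
                                             "kernel-kmeans", "linkage",
                                             "okkc"),
                                  n_reps = 1, seed = 1,
                                  consensus_method = "EACAL",
                                  linkage_method = "ward",
                                  mu_min = 0, lambda = 0.01,
                                  n_restarts = 10, views = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "mvtm_dataset"))
  vws <- dataset$views
  if (!is.null(views)) vws <- vws[views]
  labels <- dataset$labels
  diseases <- sort(unique(unlist(labels, use.names = FALSE)))
  if (length(diseases) < 2) stop("Need at least two diseases.", call. = FALSE)
  pairs <- disease_pairs(diseases)
  mats <- lapply(vws, view_matrix)

  one_pair <- function(da, db, run_seed) {
    has_a <- vapply(labels, function(l) da %in% l, TRUE)
    has_b <- vapply(labels, function(l) db %in% l, TRUE)
    keep <- names(labels)[xor(has_a, has_b)]
    if (length(keep) < 4) return(NULL)
    truth <- partition(stats::setNames(ifelse(has_a[keep], 1L, 2L), keep),
                       k = 2)
    score <- function(part) {
      ag <- agreement(part, truth)
      c(ri = ag$ri, nmi = ag$nmi)
    }
    if (method == "single-view") {
      res <- lapply(names(vws), function(nm) {
        p <- kmeans_partition(mats[[nm]][keep, , drop = FALSE], k = 2,
                              seed = run_seed, n_restarts = n_restarts)
        c(score(p))
      })
      tibble::tibble(view = names(vws),
                     ri = vapply(res, `[[`, 0, "ri"),
                     nmi = vapply(res, `[[`, 0, "nmi"))
    } else if (method == "consensus") {
      parts <- lapply(names(vws), function(nm) {
        kmeans_partition(mats[[nm]][keep, , drop = FALSE], k = 2,
                         seed = run_seed, n_restarts = n_restarts)
      })
      p <- consensus_combine(parts, k = 2, method = consensus_method,
                             seed = run_seed)
      s <- score(p)
      tibble::tibble(view = NA_character_, ri = s[["ri"]], nmi = s[["nmi"]])
    } else {
      kernels <- lapply(vws, function(v) {
        kernel_matrix(view_matrix(v)[keep, , drop = FALSE])
      })
      p <- if (method == "kernel-kmeans") {
        kernel_kmeans(combine_kernels(kernels, trace_normalize = TRUE),
                      k = 2, seed = run_seed, n_restarts = n_restarts)
      } else if (method == "linkage") {
        linkage_partition(hilbert_distance(kernels), method = linkage_method,
                          k = 2)
      } else {
        okkc(kernels, k = 2, lambda = lambda, mu_min = mu_min,
             seed = run_seed, n_restarts = n_restarts)$partition
      }
      s <- score(p)
      tibble::tibble(view = NA_character_, ri = s[["ri"]], nmi = s[["nmi"]])
    }
  }

  run_seeds <- matrix(derive_seeds(seed, nrow(pairs) * n_reps),
                      nrow(pairs), n_reps)
  rows <- list()
  skipped <- 0
  for (i in seq_len(nrow(pairs))) {
    for (rep in seq_len(n_reps)) {
      res <- one_pair(pairs$disease_a[i], pairs$disease_b[i],
                      run_seeds[i, rep])
      if (is.null(res)) { skipped <- skipped + 1; next }
      rows[[length(rows) + 1]] <- dplyr::mutate(
        res, method = method, disease_a = pairs$disease_a[i],
        disease_b = pairs$disease_b[i], rep = rep, .before = 1
      )
    }
  }
  if (skipped > 0) {
    warning(skipped / n_reps, " disease pair(s) skipped: fewer than four ",
            "genes after removing shared genes.", call. = FALSE)
  }
  detail <- dplyr::bind_rows(rows)
  group <- if (method == "single-view") c("method", "view") else "method"
  summary <- detail |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(mean_ri = mean(.data$ri), sd_ri = stats::sd(.data$ri),
                     mean_nmi = mean(.data$nmi), sd_nmi = stats::sd(.data$nmi),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(detail = detail, summary = summary, n_pairs = nrow(pairs),
         config = list(method = method, n_reps = n_reps, seed = seed,
                       consensus_method = consensus_method,
                       linkage_method = linkage_method, mu_min = mu_min,
                       lambda = lambda, views = names(vws))),
    class = "mvtm_cluster_eval"
  )
}

#' @export
print.mvtm_cluster_eval <- function(x, ...) {
  cat("<pairwise two-disease evaluation: ", x$n_pairs, " pairs, method '",
      x$config$method, "', ", x$config$n_reps, " rep(s)>\n", sep = "")
  print(x$summary)
  invisible(x)
}
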