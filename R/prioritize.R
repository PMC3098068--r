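#' Disease model profile
#'
#' The prioritization model of a disease is the average gene-by-term
#' profile of its training genes.
#'
#' @param training_profiles Numeric matrix of training gene rows (at least
#'   one non-zero row).
#' @return Numeric model vector.
#' @export
build_model <- function(training_profiles) {
  x <- as.matrix(training_profiles)
  if (nrow(x) < 1 || all(x == 0)) {
    stop("Training set is empty or all-zero; no model can be built.",
         call. = FALSE)
  }
  colMeans(x)
}

#' Pearson-correlation scores against a model profile
#'
#' The base prioritization method: each candidate row is scored by its
#' Pearson correlation with the model vector. Candidates (or models) with
#' zero variance get score 0 by convention.
#'
#' @param model Numeric model vector.
#' @param candidates A [view()] or numeric matrix of candidate rows.
#' @return Named numeric scores.
#' @export
score_correlation <- function(model, candidates) {
  x <- if (inherits(candidates, "mvtm_view")) view_matrix(candidates) else as.matrix(candidates)
  if (ncol(x) != length(model)) {
    stop("Candidate columns do not match the model dimension.", call. = FALSE)
  }
  zm <- model - mean(model)
  nm <- sqrt(sum(zm^2))
  xc <- x - rowMeans(x)
  nx <- sqrt(rowSums(xc^2))
  if (nm == 0) return(stats::setNames(rep(0, nrow(x)), rownames(x)))
  s <- drop(xc %*% zm) / (nx * nm)
  s[nx == 0] <- 0
  stats::setNames(s, rownames(x))
}

#' Ranking list from scores
#'
#' Orders candidates by decreasing score, breaking ties by ascending
#' candidate id, and attaches rank ratios (position divided by the number
#' of candidates, in `(0, 1]`).
#'
#' @param scores Named numeric vector (names are candidate ids).
#' @param ids Candidate ids; defaults to `names(scores)`.
#' @return A tibble of class `mvtm_ranking` with columns `candidate_id`,
#'   `score`, `rank`, `rank_ratio`.
#' @export
rank_candidates <- function(scores, ids = names(scores)) {
  if (length(scores) < 1) stop("Need at least one candidate.", call. = FALSE)
  ids <- ids %||% as.character(seq_along(scores))
  ord <- order(-scores, ids)
  n <- length(scores)
  out <- tibble::tibble(
    candidate_id = ids[ord],
    score = as.numeric(scores[ord]),
    rank = seq_len(n),
    rank_ratio = seq_len(n) / n
  )
  class(out) <- c("mvtm_ranking", class(out))
  out
}

#' Fuse aligned score vectors
#'
#' Element-wise mean or maximum of per-view scores over one candidate set.
#'
#' @param score_lists List of at least two named numeric vectors over the
#'   same candidates (any order; aligned by name when names are present).
#' @param method `"average"` or `"max"`.
#' @return Named numeric fused scores.
#' @export
fuse_scores <- function(score_lists, method = c("average", "max")) {
  method <- match.arg(method)
  if (length(score_lists) < 2) stop("Need at least two score vectors.",
                                    call. = FALSE)
  ids <- names(score_lists[[1]])
  aligned <- lapply(score_lists, function(s) {
    if (!is.null(ids)) {
      if (is.null(names(s)) || !setequal(names(s), ids)) {
        stop("Score vectors cover different candidate sets.", call. = FALSE)
      }
      s[ids]
    } else {
      if (length(s) != length(score_lists[[1]])) {
        stop("Score vectors cover different candidate sets.", call. = FALSE)
      }
      s
    }
  })
  m <- do.call(cbind, aligned)
  out <- if (method == "average") rowMeans(m) else apply(m, 1, max)
  stats::setNames(as.numeric(out), ids)
}

# Rows centered and scaled to unit norm, for fast correlation scoring.
standardize_rows <- function(x) {
  xc <- x - rowMeans(x)
  nx <- sqrt(rowSums(xc^2))
  nx[nx == 0] <- 1
  xc / nx
}

# AUC of a single positive among negatives, midrank tie handling.
single_positive_auc <- function(pos_score, neg_scores) {
  (sum(pos_score > neg_scores) + 0.5 * sum(pos_score == neg_scores)) /
    length(neg_scores)
}

#' Leave-one-out prioritization benchmark
#'
#' For every disease and every member gene, the member (the "defector") is
#' removed from the training set and inserted among randomly drawn
#' unlabeled candidate genes; the trained model then ranks the test set and
#' the defector's recovery is scored as `error = 1 - AUC` (the defector
#' being the sole positive, AUC computed with midrank ties). Candidates are
#' re-drawn for each defector in each repetition.
#'
#' @param dataset A [multiview_dataset()] with IDF (or latent) views.
#' @param method One of `"single-view"`, `"average"`, `"max"`,
#'   `"order-statistics"`, `"one-svm"`.
#' @param n_candidates Random unlabeled genes per test set (default 99).
#' @param n_reps Repetitions (fresh candidate draws) per defector.
#' @param seed Integer seed.
#' @param nu,mu_min One-class SVM parameters (`mu_min` defaults to `1/N`,
#'   the uniform kernel combination).
#' @param views Optional subset of view names to use.
#' @param calibration_samples Null-sample size for the order-statistics
#'   p-value calibration.
#' @return An object of class `mvtm_loo`: list with `detail` (tibble with
#'   one row per defector x repetition), `summary` (mean/sd error per
#'   method or view), and `config`.
#' @export
loo_benchmark <- function(dataset,
                          method = c("single-view", "average", "max",
                                     "order-statistics", "one-svm"),
                          n_candidates = 99, n_reps = 1, seed = 1,
                          nu = 0.5, mu_min = NULL, views = NULL,
                          calibration_samples = 10000) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "mvtm_dataset"))
  vws <- dataset$views
  if (!is.null(views)) vws <- vws[views]
  n_views <- length(vws)
  if (method != "single-view" && n_views < 2) {
    stop("Integration methods need at least two views.", call. = FALSE)
  }
  genes <- dataset$gene_ids
  labels <- dataset$labels
  pool <- setdiff(genes, names(labels))
  if (length(pool) < n_candidates) {
    stop("Candidate pool (", length(pool), " unlabeled genes) is smaller ",
         "than `n_candidates`.", call. = FALSE)
  }
  # genes with an all-zero profile in every view never enter training sets
  zero_all <- Reduce(intersect, lapply(vws, zero_genes)) %||% character(0)
  diseases <- sort(unique(unlist(labels, use.names = FALSE)))
  members <- lapply(stats::setNames(diseases, diseases), function(d) {
    setdiff(names(labels)[vapply(labels, function(l) d %in% l, TRUE)],
            zero_all)
  })
  if (any(lengths(members) < 2)) {
    stop("Every disease needs at least two trainable genes.", call. = FALSE)
  }
  defectors <- tibble::tibble(
    disease = rep(names(members), lengths(members)),
    defector = unlist(members, use.names = FALSE)
  )
  n_def <- nrow(defectors)

  # Per-view correlation scores of every gene against every defector model.
  score_mats <- NULL
  if (method != "one-svm") {
    score_mats <- lapply(vws, function(v) {
      x <- view_matrix(v)
      z <- standardize_rows(x)
      models <- t(matrix(vapply(seq_len(n_def), function(i) {
        tr <- setdiff(members[[defectors$disease[i]]], defectors$defector[i])
        build_model(x[tr, , drop = FALSE])
      }, numeric(ncol(x))), nrow = ncol(x)))
      zm <- standardize_rows(models)
      s <- z %*% t(zm)                      # genes x defectors
      rownames(s) <- genes
      s
    })
  }

  # One-SVM: per-defector alpha on the combined kernel, scores for all genes.
  svm_scores <- NULL
  if (method == "one-svm") {
    mu_min <- mu_min %||% (1 / n_views)
    kernels <- lapply(vws, kernel_matrix)
    g_hat <- lapply(kernels, function(k) k$gram / k$trace_r)
    uniform <- abs(mu_min - 1 / n_views) < 1e-12
    omega_avg <- Reduce(`+`, g_hat) / n_views
    svm_scores <- matrix(NA_real_, length(genes), n_def,
                         dimnames = list(genes, NULL))
    for (i in seq_len(n_def)) {
      tr <- setdiff(members[[defectors$disease[i]]], defectors$defector[i])
      ub <- 1 / (nu * length(tr))
      if (uniform) {
        omega <- omega_avg
        a <- solve_box_simplex_qp(omega[tr, tr], ub)$alpha
      } else {
        fit <- fit_one_svm_fusion(kernels, tr, nu = nu, mu_min = mu_min,
                                  check = FALSE)
        omega <- fit$combined_kernel$gram
        a <- fit$alphas
      }
      raw <- drop(omega[, tr, drop = FALSE] %*% a)
      mn <- sqrt(max(drop(crossprod(a, omega[tr, tr] %*% a)), 0))
      self <- pmax(diag(omega), 0)
      den <- mn * sqrt(self)
      svm_scores[, i] <- pmin(pmax(ifelse(den > 1e-12, raw / pmax(den, 1e-300), 0),
                                   -1), 1)
    }
  }

  qcal <- if (method == "order-statistics") {
    calibrate_q(n_views, n_samples = calibration_samples,
                seed = derive_seeds(seed, 1))
  } else {
    NULL
  }

  task_error <- function(task_ids, def_idx, defector) {
    # returns error per reporting unit (one per view for single-view)
    if (method == "single-view") {
      vapply(score_mats, function(s) {
        sc <- s[task_ids, def_idx]
        1 - single_positive_auc(sc[defector], sc[setdiff(task_ids, defector)])
      }, numeric(1))
    } else if (method %in% c("average", "max")) {
      sc <- vapply(score_mats, function(s) s[task_ids, def_idx],
                   numeric(length(task_ids)))
      f <- if (method == "average") rowMeans(sc) else apply(sc, 1, max)
      names(f) <- task_ids
      1 - single_positive_auc(f[defector], f[setdiff(task_ids, defector)])
    } else if (method == "order-statistics") {
      n <- length(task_ids)
      ratios <- vapply(score_mats, function(s) {
        sc <- s[task_ids, def_idx]
        r <- numeric(n)
        r[order(-sc, task_ids)] <- seq_len(n)
        r / n
      }, numeric(n))
      p <- q_pvalue(q_statistic_rows(ratios), qcal)
      names(p) <- task_ids
      1 - single_positive_auc(-p[defector], -p[setdiff(task_ids, defector)])
    } else {
      sc <- svm_scores[task_ids, def_idx]
      1 - single_positive_auc(sc[defector], sc[setdiff(task_ids, defector)])
    }
  }

  rep_seeds <- derive_seeds(seed + 1, n_reps * n_def)
  rows <- vector("list", n_reps * n_def)
  idx <- 0
  for (rep in seq_len(n_reps)) {
    for (i in seq_len(n_def)) {
      idx <- idx + 1
      cand <- with_seed(rep_seeds[idx], sample(pool, n_candidates))
      task <- c(defectors$defector[i], cand)
      err <- task_error(task, i, defectors$defector[i])
      rows[[idx]] <- tibble::tibble(
        method = method,
        view = if (method == "single-view") names(vws) else NA_character_,
        disease = defectors$disease[i],
        defector = defectors$defector[i],
        rep = rep,
        error = as.numeric(err)
      )
    }
  }
  detail <- dplyr::bind_rows(rows)
  group <- if (method == "single-view") c("method", "view") else "method"
  summary <- detail |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(mean_error = mean(.data$error),
                     sd_error = stats::sd(.data$error),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(detail = detail, summary = summary,
         config = list(method = method, n_candidates = n_candidates,
                       n_reps = n_reps, seed = seed, nu = nu,
                       mu_min = mu_min, views = names(vws))),
    class = "mvtm_loo"
  )
}

#' @export
print.mvtm_loo <- function(x, ...) {
  cat("<leave-one-out benchmark: method '", x$config$method, "', ",
      x$config$n_reps, " rep(s), ", x$config$n_candidates,
      " candidates>\n", sep = "")
  print(x$summary)
  invisible(x)
}
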