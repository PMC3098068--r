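#' Run a configured end-to-end experiment
#'
#' Ties generation, view construction, optional LSI reduction, and
#' evaluation into one reproducible call. The configuration is a nested
#' list:
#' \describe{
#'   \item{benchmark}{Arguments for [generate_benchmark()] (including
#'     `seed`).}
#'   \item{reduction}{`list(type = "none")` or `list(type = "lsi",
#'     fraction = 5e-4)`; LSI is fitted per view on the full gene
#'     universe.}
#'   \item{task}{`"prioritize"` or `"cluster"`.}
#'   \item{methods}{Character vector of methods for the task (see
#'     [loo_benchmark()] / [pairwise_disease_eval()]).}
#'   \item{evaluation}{Task options: `n_reps`, `seed`, and for
#'     prioritization `n_candidates`, `nu`, `mu_min`; for clustering
#'     `consensus_method`, `linkage_method`, `mu_min`, `lambda`.}
#' }
#'
#' @param config Configuration list as above.
#' @param out_dir Optional directory; when given, the report JSON and the
#'   (possibly reduced) views are written there.
#' @return An object of class `mvtm_experiment`: list with `task`,
#'   `reports` (one evaluation object per method), `summary` (combined
#'   tibble), `config`, and `config_hash`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(is.list(config), !is.null(config$benchmark),
            config$task %in% c("prioritize", "cluster"))
  bench <- do.call(generate_benchmark, config$benchmark)
  dataset <- bench$dataset

  red <- config$reduction %||% list(type = "none")
  if (identical(red$type, "lsi")) {
    frac <- red$fraction %||% 5e-4
    views <- lapply(dataset$views, function(v) {
      dec <- lsi_decompose(v, threshold_fraction = frac)
      lsi_project(v, dec)
    })
    dataset <- multiview_dataset(views, dataset$labels)
  }

  ev <- config$evaluation %||% list()
  methods <- config$methods %||%
    if (config$task == "prioritize") "single-view" else "single-view"
  reports <- lapply(stats::setNames(methods, methods), function(m) {
    if (config$task == "prioritize") {
      loo_benchmark(dataset, method = m,
                    n_candidates = ev$n_candidates %||% 99,
                    n_reps = ev$n_reps %||% 1,
                    seed = ev$seed %||% 1,
                    nu = ev$nu %||% 0.5, mu_min = ev$mu_min)
    } else {
      pairwise_disease_eval(dataset, method = m,
                            n_reps = ev$n_reps %||% 1,
                            seed = ev$seed %||% 1,
                            consensus_method = ev$consensus_method %||% "EACAL",
                            linkage_method = ev$linkage_method %||% "ward",
                            mu_min = ev$mu_min %||% 0,
                            lambda = ev$lambda %||% 0.01)
    }
  })
  summary <- dplyr::bind_rows(lapply(reports, `[[`, "summary"))
  hash <- digest_config(config)
  out <- structure(
    list(task = config$task, reports = reports, summary = summary,
         config = config, config_hash = hash,
         version = as.character(utils::packageVersion("mvtm"))),
    class = "mvtm_experiment"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(task = out$task, summary = summary, config_hash = hash,
           version = out$version),
      file.path(out_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    for (v in dataset$views) {
      write_view(v, out_dir)
    }
  }
  out
}

# Stable configuration fingerprint (order-independent within lists).
digest_config <- function(config) {
  canon <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # polynomial rolling hash over the canonical JSON string (double-safe)
  bytes <- utf8ToInt(canon)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.mvtm_experiment <- function(x, ...) {
  cat("<experiment: task '", x$task, "', ", length(x$reports),
      " method(s), config ", x$config_hash, ">\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Paired comparison of evaluation reports
#'
#' Compares methods pairwise by a paired t-test on their per-repetition
#' metric values (repetition means), the pairing being the shared
#' repetition structure. Self-comparisons or zero-variance differences
#' yield `NA` p-values with a `degenerate` flag.
#'
#' @param reports Named list of `mvtm_loo` or `mvtm_cluster_eval` objects
#'   sharing the same repetition structure (e.g. `$reports` of an
#'   experiment).
#' @param metric `"error"`, `"ri"`, or `"nmi"`.
#' @return Tibble with one row per method pair: mean difference,
#'   `statistic`, `p_value`, `degenerate`.
#' @export
compare_methods <- function(reports, metric = c("error", "ri", "nmi")) {
  metric <- match.arg(metric)
  if (length(reports) < 2) stop("Need at least two reports.", call. = FALSE)
  nms <- names(reports) %||% paste0("method", seq_along(reports))
  per_rep <- lapply(reports, function(r) {
    d <- r$detail
    if (!metric %in% names(d)) {
      stop("Metric '", metric, "' not present in report.", call. = FALSE)
    }
    d |>
      dplyr::group_by(.data$rep) |>
      dplyr::summarise(value = mean(.data[[metric]]), .groups = "drop") |>
      dplyr::arrange(.data$rep)
  })
  n_rep <- vapply(per_rep, nrow, integer(1))
  if (length(unique(n_rep)) != 1) {
    stop("Reports have unequal repetition counts: ",
         paste(n_rep, collapse = ", "), call. = FALSE)
  }
  idx <- utils::combn(length(reports), 2)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    x <- per_rep[[i1]]$value
    y <- per_rep[[i2]]$value
    diffs <- x - y
    tt <- if (length(diffs) >= 2 && stats::sd(diffs) > 0) {
      tryCatch(t.test(x, y, paired = TRUE), error = function(e) NULL)
    } else {
      NULL
    }
    if (is.null(tt)) {
      tibble::tibble(method_a = nms[i1], method_b = nms[i2],
                     mean_diff = mean(diffs), statistic = NA_real_,
                     p_value = NA_real_, degenerate = TRUE)
    } else {
      tibble::tibble(method_a = nms[i1], method_b = nms[i2],
                     mean_diff = unname(tt$estimate),
                     statistic = unname(tt$statistic),
                     p_value = tt$p.value, degenerate = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}
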