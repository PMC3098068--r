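#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a leave-one-out report
#'
#' @param x An `mvtm_loo` object.
#' @param ... Unused.
#' @return The per-defector/repetition detail tibble.
#' @export
tidy.mvtm_loo <- function(x, ...) x$detail

#' @rdname tidy.mvtm_loo
#' @export
glance.mvtm_loo <- function(x, ...) {
  tibble::tibble(
    method = x$config$method,
    mean_error = mean(x$detail$error),
    sd_error = stats::sd(x$detail$error),
    n_defectors = length(unique(x$detail$defector)),
    n_reps = x$config$n_reps,
    n_candidates = x$config$n_candidates
  )
}

#' Tidy a pairwise clustering evaluation
#'
#' @param x An `mvtm_cluster_eval` object.
#' @param ... Unused.
#' @return The per-pair/repetition detail tibble.
#' @export
tidy.mvtm_cluster_eval <- function(x, ...) x$detail

#' @rdname tidy.mvtm_cluster_eval
#' @export
glance.mvtm_cluster_eval <- function(x, ...) {
  tibble::tibble(
    method = x$config$method,
    mean_ri = mean(x$detail$ri),
    sd_ri = stats::sd(x$detail$ri),
    mean_nmi = mean(x$detail$nmi),
    sd_nmi = stats::sd(x$detail$nmi),
    n_pairs = x$n_pairs,
    n_reps = x$config$n_reps
  )
}

#' Tidy a one-class SVM fusion model
#'
#' @param x An `mvtm_onesvm` object.
#' @param ... Unused.
#' @return Tibble with one row per kernel: weight `mu`.
#' @export
tidy.mvtm_onesvm <- function(x, ...) {
  tibble::tibble(kernel = seq_along(x$mu), mu = x$mu)
}

#' @rdname tidy.mvtm_onesvm
#' @export
glance.mvtm_onesvm <- function(x, ...) {
  tibble::tibble(t_value = x$t_value, nu = x$nu, mu_min = x$mu_min,
                 n_kernels = length(x$mu),
                 n_training = length(x$training_ids))
}

#' Tidy an OKKC state
#'
#' @param x An `mvtm_okkc` object.
#' @param ... Unused.
#' @return Tibble with one row per kernel: weight `mu`.
#' @export
tidy.mvtm_okkc <- function(x, ...) {
  tibble::tibble(kernel = seq_along(x$mu), mu = x$mu)
}

#' @rdname tidy.mvtm_okkc
#' @export
glance.mvtm_okkc <- function(x, ...) {
  tibble::tibble(k = x$k, lambda = x$lambda, mu_min = x$mu_min,
                 iterations = x$iterations,
                 objective = utils::tail(x$objective_trace, 1))
}

#' Tidy a partition agreement
#'
#' @param x An `mvtm_agreement` object.
#' @param ... Unused.
#' @return One-row tibble with pair counts, RI and NMI.
#' @export
tidy.mvtm_agreement <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c, d = x$d,
                 ri = x$ri, mi = x$mi, nmi = x$nmi, n = x$n)
}

#' Plot a leave-one-out report
#'
#' Boxplots of per-defector errors by method (or by view for single-view
#' reports).
#'
#' @param object An `mvtm_loo` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mvtm_loo <- function(object, ...) {
  d <- object$detail
  d$unit <- if (all(is.na(d$view))) d$method else d$view
  ggplot2::ggplot(d, ggplot2::aes(x = .data$unit, y = .data$error)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "1 - AUC (leave-one-out error)") +
    ggplot2::theme_minimal()
}

#' Plot a pairwise clustering evaluation
#'
#' Mean Rand index and NMI with one standard deviation, per method/view.
#'
#' @param object An `mvtm_cluster_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mvtm_cluster_eval <- function(object, ...) {
  d <- object$detail
  d$unit <- if (all(is.na(d$view))) d$method else d$view
  long <- tidyr::pivot_longer(d, c("ri", "nmi"), names_to = "metric",
                              values_to = "value")
  long$metric <- toupper(long$metric)
  stats <- long |>
    dplyr::group_by(.data$unit, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$unit, y = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "agreement with disease labels") +
    ggplot2::theme_minimal()
}

#' Plot an LSI spectrum
#'
#' Scree plot of the singular values with the spectrum-fraction threshold
#' and the selected rank.
#'
#' @param object An `mvtm_lsi` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mvtm_lsi <- function(object, ...) {
  vals <- if (object$use == "squared") {
    object$singular_values^2
  } else {
    object$singular_values
  }
  d <- tibble::tibble(factor = seq_along(vals), value = vals)
  thr <- object$threshold_fraction * sum(vals)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$factor, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$k_selected, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "latent factor", y = "singular value") +
    ggplot2::theme_minimal()
}
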