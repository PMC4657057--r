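#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-resample optimizer cost of a run
#'
#' Function evaluations spent by the optimizer per estimate, against the
#' processing step, with a block-mean trend line. Warm-started variants show
#' the cost falling as the fingerprint-to-optimum relation is learned;
#' bypassed estimates sit at zero.
#'
#' @param object An `fpr_run`.
#' @param block Block size for the mean trend (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fpr_run
#' @export
autoplot.fpr_run <- function(object, block = 20, ...) {
  recs <- object$records
  recs$block <- (recs$step - 1) %/% block
  trend <- recs |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(step = mean(.data$step), n_evals = mean(.data$n_evals))
  ggplot2::ggplot(recs, ggplot2::aes(x = .data$step, y = .data$n_evals)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = trend, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "resample (processing order)",
                  y = "optimizer function evaluations",
                  title = paste0(object$model$name, ", ", object$plan$option)) +
    ggplot2::theme_minimal()
}

#' Plot a speed-accuracy trade-off curve
#'
#' Percentile-estimate error against cumulative function evaluations on
#' log-log axes.
#'
#' @param object An `fpr_accuracy_curve` (see [accuracy_curve()]).
#' @param ... Further curves to overlay.
#' @return A ggplot object.
#' @method autoplot fpr_accuracy_curve
#' @export
autoplot.fpr_accuracy_curve <- function(object, ...) {
  curves <- c(list(object), Filter(function(x) inherits(x, "fpr_accuracy_curve"),
                                   list(...)))
  df <- dplyr::bind_rows(lapply(curves, function(cv) {
    dplyr::mutate(tibble::as_tibble(cv), variant = attr(cv, "variant"))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cum_cost, y = .data$delta,
                                   colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cumulative function evaluations",
                  y = "percentile-estimate error",
                  colour = NULL,
                  title = paste("parameter:", attr(object, "parameter"))) +
    ggplot2::theme_minimal()
}

#' Scatter of fingerprints against optima in a run's training pool
#'
#' Shows the learned relation for one fingerprint component and one
#' parameter: affine for the exponential toy, curved (and, with a first
#' order fingerprint only, non-unique) for the regression toy.
#'
#' @param run An `fpr_run` of a fingerprint variant.
#' @param data Original data set.
#' @param fp_component Fingerprint component to plot (default 1).
#' @param parameter Parameter label (default: first).
#' @return A ggplot object.
#' @export
plot_fingerprint_relation <- function(run, data, fp_component = 1,
                                      parameter = run$model$par_names[1]) {
  resamples <- run_resamples(run, data)
  recs <- run$records
  fps <- vapply(recs$index, function(b) {
    f <- compute_fingerprint(run$model, resamples[[b]], run$theta0,
                             g = run$plan$g)
    if (f$valid) f$values[fp_component] else NA_real_
  }, numeric(1))
  df <- tibble::tibble(fingerprint = fps,
                       optimum = recs[[paste0("estimate_", parameter)]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fingerprint, y = .data$optimum)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::labs(x = paste0("fingerprint component ", fp_component),
                  y = parameter) +
    ggplot2::theme_minimal()
}
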