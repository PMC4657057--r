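#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fingerprint-resampling run
#'
#' Returns the per-resample records: one row per estimate in processing
#' order, with start and estimate components, evaluation counts, and the
#' bypassed/prioritized flags.
#'
#' @param x An `fpr_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fpr_run
#' @export
tidy.fpr_run <- function(x, ...) {
  x$records
}

#' One-row summary of a fingerprint-resampling run
#'
#' @param x An `fpr_run`.
#' @param ... Unused.
#' @return A tibble with the variant, budget, bypass/convergence counts,
#'   total function-evaluation cost, and the original optimum components.
#' @method glance fpr_run
#' @export
glance.fpr_run <- function(x, ...) {
  recs <- x$records
  out <- tibble::tibble(
    model = x$model$name,
    option = x$plan$option,
    g = x$plan$g,
    p = x$plan$p,
    B = nrow(recs),
    n_bypassed = sum(recs$bypassed),
    n_prioritized = sum(recs$prioritized),
    optimizer_evals = sum(recs$n_evals),
    fingerprint_evals = sum(recs$fingerprint_cost),
    total_cost = total_cost(recs),
    mean_evals_per_fit = mean(recs$n_evals[!recs$bypassed])
  )
  th <- stats::setNames(as.list(x$theta0),
                        paste0("theta0_", x$model$par_names))
  dplyr::bind_cols(out, tibble::as_tibble(th))
}

#' Tidy a fitted fingerprint interpolator
#'
#' @param x An `fp_interpolator`.
#' @param ... Unused.
#' @return A tibble with one row per parameter dimension: the selected
#'   kernel width and ridge penalty and the leave-one-out RMS error.
#' @method tidy fp_interpolator
#' @export
tidy.fp_interpolator <- function(x, ...) {
  tibble::tibble(
    dimension = seq_along(x$models),
    width = vapply(x$models, function(m) m$width, numeric(1)),
    lambda = vapply(x$models, function(m) m$lambda, numeric(1)),
    loo_rmse = x$loo_error,
    training_size = x$training_size
  )
}
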