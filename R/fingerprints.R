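#' Derivative-based fingerprint of a resampled data set
#'
#' Summarizes a resampled data set by finite-difference partial derivatives
#' of *its* log-likelihood evaluated at the *original* data set's optimum.
#' Order `g = 1` keeps the gradient; `g = 2` appends the unique (upper
#' triangular) Hessian entries. Because the expansion point is shared across
#' resamples, fingerprints are directly comparable and carry information on
#' where each resample's own optimum lies.
#'
#' Stencils are central differences with per-dimension step
#' `h_k = step_scale * (1 + |theta0_k|)`. Function evaluations are counted
#' exactly: `2 d` for the gradient; `2 d + 1` more points for the pure
#' second differences (the gradient points are reused, the center adds one)
#' plus `4` per off-diagonal pair, giving `2 d + 1 + 2 d (d - 1)` in total
#' for `g = 2`.
#'
#' If the objective is non-finite at any stencil point (e.g. the resample
#' falls outside a GEV support region at `theta0`), the fingerprint is
#' flagged invalid instead of erroring; the driver then routes that resample
#' to a full optimization.
#'
#' @param model An [objective_model].
#' @param data The (resampled) data set.
#' @param theta0 Expansion point, normally the original optimum.
#' @param g Derivative order, 1 or 2.
#' @param step_scale Relative step size (default 1e-4).
#' @return An object of class `fingerprint`: list with `values` (numeric,
#'   length `d` or `d + d(d+1)/2`), `order`, `eval_cost`, `valid`.
#' @examples
#' m <- model_exponential()
#' d <- data.frame(x = c(1, 3))
#' compute_fingerprint(m, d, theta0 = 2, g = 1)
#' @export
compute_fingerprint <- function(model, data, theta0, g = 1,
                                step_scale = 1e-4) {
  stopifnot(g %in% c(1, 2), length(theta0) == model$dim)
  f <- bind_loglik(model, data)
  d <- model$dim
  h <- step_scale * (1 + abs(theta0))
  n_evals <- 0L
  bad <- FALSE
  ev <- function(theta) {
    n_evals <<- n_evals + 1L
    v <- f(theta)
    if (!is.finite(v)) bad <<- TRUE
    v
  }
  shift <- function(k, s) { th <- theta0; th[k] <- th[k] + s; th }

  fplus <- numeric(d); fminus <- numeric(d)
  for (k in seq_len(d)) {
    fplus[k] <- ev(shift(k, h[k]))
    fminus[k] <- ev(shift(k, -h[k]))
    if (bad) {
      return(new_fingerprint(numeric(0), g, n_evals, valid = FALSE))
    }
  }
  grad <- (fplus - fminus) / (2 * h)
  if (g == 1) {
    return(new_fingerprint(grad, 1L, n_evals, valid = TRUE))
  }

  f0 <- ev(theta0)
  if (bad) return(new_fingerprint(numeric(0), g, n_evals, valid = FALSE))
  hess <- matrix(NA_real_, d, d)
  for (k in seq_len(d)) {
    hess[k, k] <- (fplus[k] - 2 * f0 + fminus[k]) / h[k]^2
  }
  if (d > 1) {
    for (k in seq_len(d - 1)) {
      for (l in (k + 1):d) {
        th <- function(sk, sl) {
          t0 <- theta0; t0[k] <- t0[k] + sk * h[k]; t0[l] <- t0[l] + sl * h[l]; t0
        }
        fpp <- ev(th(1, 1)); fpm <- ev(th(1, -1))
        fmp <- ev(th(-1, 1)); fmm <- ev(th(-1, -1))
        if (bad) return(new_fingerprint(numeric(0), g, n_evals, valid = FALSE))
        hess[k, l] <- (fpp - fpm - fmp + fmm) / (4 * h[k] * h[l])
      }
    }
  }
  vals <- c(grad, hess[upper.tri(hess, diag = TRUE)])
  new_fingerprint(vals, 2L, n_evals, valid = TRUE)
}

new_fingerprint <- function(values, order, eval_cost, valid) {
  structure(list(values = as.numeric(values), order = as.integer(order),
                 eval_cost = as.integer(eval_cost), valid = valid),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> order", x$order,
      if (x$valid) "" else "(invalid)",
      "\n  values:", format(x$values, digits = 4),
      "\n  eval_cost:", x$eval_cost, "\n")
  invisible(x)
}

#' Expected evaluation cost of a fingerprint stencil
#'
#' @param dim Parameter dimension.
#' @param g Derivative order, 1 or 2.
#' @return Integer count of objective evaluations.
#' @export
fingerprint_eval_cost <- function(dim, g) {
  stopifnot(g %in% c(1, 2))
  if (g == 1) as.integer(2 * dim) else as.integer(2 * dim + 1 + 2 * dim * (dim - 1))
}

#' Squared Euclidean distance between fingerprints
#'
#' @param a,b Valid [compute_fingerprint()] results of the same order.
#' @return Nonnegative scalar; zero iff the value vectors are equal.
#' @export
fingerprint_distance <- function(a, b) {
  if (a$order != b$order || length(a$values) != length(b$values)) {
    stop("Fingerprints have mismatched order or length.", call. = FALSE)
  }
  if (!a$valid || !b$valid) {
    stop("Both fingerprints must be valid.", call. = FALSE)
  }
  sum((a$values - b$values)^2)
}
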