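#' Default initial simplex (basic-optimizer convention)
#'
#' Vertex 1 is the start; vertex `k + 1` perturbs component `k`: multiplied
#' by 1.05 when nonzero, set to 0.00025 when zero (the convention of the
#' classic simplex implementations in common numerical environments).
#'
#' @param start Numeric start vector.
#' @return A `(dim + 1) x dim` matrix of vertices, one per row.
#' @export
init_simplex_default <- function(start) {
  d <- length(start)
  V <- matrix(rep(start, d + 1), d + 1, d, byrow = TRUE)
  for (k in seq_len(d)) {
    V[k + 1, k] <- if (start[k] != 0) 1.05 * start[k] else 0.00025
  }
  V
}

#' Prediction-error-scaled initial simplex
#'
#' When the start is a predicted optimum, the simplex should initially
#' search only an area matching the prediction's uncertainty. Vertex `k + 1`
#' offsets component `k` additively by `max(eps[k], tol_x)`; the `tol_x`
#' floor keeps the simplex nondegenerate when the prediction error is
#' essentially zero.
#'
#' @param start Numeric start vector (predicted optimum).
#' @param eps Per-dimension nonnegative prediction errors.
#' @param tol_x Parameter convergence tolerance (floor for the offset).
#' @return A `(dim + 1) x dim` matrix of vertices, one per row.
#' @export
init_simplex_predicted <- function(start, eps, tol_x = 1e-6) {
  d <- length(start)
  stopifnot(length(eps) == d, all(eps >= 0))
  V <- matrix(rep(start, d + 1), d + 1, d, byrow = TRUE)
  for (k in seq_len(d)) {
    V[k + 1, k] <- start[k] + max(eps[k], tol_x)
  }
  V
}

#' Nelder-Mead simplex minimization with exact evaluation accounting
#'
#' Standard Nelder-Mead with reflection 1, expansion 2, contraction 0.5 and
#' shrink 0.5. Convergence is declared when both the maximum infinity-norm
#' distance between vertices and the maximum difference between their
#' function values fall below their tolerances. Every objective call is
#' counted, including the initial vertex evaluations. Objectives may return
#' `Inf` (infeasible region); at least one initial vertex must be finite.
#'
#' @param objective `function(theta) -> scalar` to minimize.
#' @param simplex Initial vertex matrix from [init_simplex_default()] or
#'   [init_simplex_predicted()].
#' @param tol_x,tol_f Convergence tolerances (both default 1e-6).
#' @param max_evals Evaluation budget (default `2000 * dim`).
#' @return List with `optimum`, `value`, `n_evals`, `converged`.
#' @examples
#' nelder_mead(function(th) (th - 3)^2, init_simplex_default(0))
#' @export
nelder_mead <- function(objective, simplex, tol_x = 1e-6, tol_f = 1e-6,
                        max_evals = NULL) {
  V <- as.matrix(simplex)
  d <- ncol(V)
  stopifnot(nrow(V) == d + 1)
  if (is.null(max_evals)) max_evals <- 2000 * d
  n_evals <- 0L
  ev <- function(theta) {
    n_evals <<- n_evals + 1L
    v <- objective(theta)
    if (is.na(v)) Inf else v
  }
  fv <- apply(V, 1, ev)
  if (all(!is.finite(fv))) {
    stop("Objective is non-finite at every initial vertex.", call. = FALSE)
  }

  rho <- 1; chi <- 2; psi <- 0.5; sigma <- 0.5
  repeat {
    ord <- order(fv)
    V <- V[ord, , drop = FALSE]
    fv <- fv[ord]
    spread_x <- max(apply(V, 2, function(col) max(col) - min(col)))
    spread_f <- if (all(is.finite(fv))) max(fv) - min(fv) else Inf
    if (spread_x < tol_x && spread_f < tol_f) {
      return(list(optimum = V[1, ], value = fv[1], n_evals = n_evals,
                  converged = TRUE))
    }
    if (n_evals >= max_evals) {
      return(list(optimum = V[1, ], value = fv[1], n_evals = n_evals,
                  converged = FALSE))
    }
    xbar <- colMeans(V[seq_len(d), , drop = FALSE])
    worst <- V[d + 1, ]
    xr <- xbar + rho * (xbar - worst)
    fr <- ev(xr)
    if (fr < fv[1]) {
      xe <- xbar + rho * chi * (xbar - worst)
      fe <- ev(xe)
      if (fe < fr) { V[d + 1, ] <- xe; fv[d + 1] <- fe }
      else { V[d + 1, ] <- xr; fv[d + 1] <- fr }
    } else if (fr < fv[d]) {
      V[d + 1, ] <- xr; fv[d + 1] <- fr
    } else {
      do_shrink <- FALSE
      if (fr < fv[d + 1]) {
        xc <- xbar + psi * rho * (xbar - worst)
        fc <- ev(xc)
        if (fc <= fr) { V[d + 1, ] <- xc; fv[d + 1] <- fc }
        else do_shrink <- TRUE
      } else {
        xcc <- xbar - psi * (xbar - worst)
        fcc <- ev(xcc)
        if (fcc < fv[d + 1]) { V[d + 1, ] <- xcc; fv[d + 1] <- fcc }
        else do_shrink <- TRUE
      }
      if (do_shrink) {
        for (i in 2:(d + 1)) {
          V[i, ] <- V[1, ] + sigma * (V[i, ] - V[1, ])
          fv[i] <- ev(V[i, ])
        }
      }
    }
  }
}

#' Maximize a model's likelihood on a data set
#'
#' Convenience wrapper: binds the model objective (negated log-likelihood
#' with `Inf` outside the constraints) to `data`, builds the requested
#' initial simplex, and runs [nelder_mead()].
#'
#' @param model An [objective_model].
#' @param data Data set.
#' @param start Start vector (default: the model's naive start).
#' @param eps Optional per-dimension prediction errors; when supplied the
#'   simplex is built with [init_simplex_predicted()], otherwise with
#'   [init_simplex_default()].
#' @param tol_x,tol_f,max_evals Passed to [nelder_mead()].
#' @return The [nelder_mead()] result list.
#' @export
fit_model <- function(model, data, start = NULL, eps = NULL,
                      tol_x = 1e-6, tol_f = 1e-6, max_evals = NULL) {
  if (is.null(start)) start <- model$naive_start(data)
  obj <- bind_objective(model, data)
  simplex <- if (is.null(eps)) init_simplex_default(start)
             else init_simplex_predicted(start, eps, tol_x)
  nelder_mead(obj, simplex, tol_x = tol_x, tol_f = tol_f,
              max_evals = max_evals)
}
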