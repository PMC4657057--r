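#' Training pool of (fingerprint, optimum) couples
#'
#' Accumulates solved resamples for the interpolator. Each couple stores the
#' fingerprint values, the optimized parameter vector, the original resample
#' index, and per-dimension flags marking optima that sit on a box
#' constraint (such optima are excluded when fitting, because an active
#' constraint breaks the smooth fingerprint-optimum relation).
#'
#' @param fp_length Length of the fingerprint value vector.
#' @param dim Parameter dimension.
#' @return An empty object of class `training_pool`.
#' @export
new_training_pool <- function(fp_length, dim) {
  structure(list(F = matrix(numeric(0), 0, fp_length),
                 Theta = matrix(numeric(0), 0, dim),
                 index = integer(0),
                 boundary = matrix(logical(0), 0, dim)),
            class = "training_pool")
}

#' Add a solved couple to the pool
#'
#' @param pool A [new_training_pool()] object.
#' @param fingerprint A valid `fingerprint`.
#' @param optimum Optimized parameter vector.
#' @param index Original resample index (must be new to the pool).
#' @param lower,upper Box constraints used to flag boundary optima
#'   (within absolute tolerance `btol`).
#' @param btol Boundary tolerance (default 1e-6).
#' @return The grown pool.
#' @export
pool_add <- function(pool, fingerprint, optimum, index, lower, upper,
                     btol = 1e-6) {
  stopifnot(inherits(pool, "training_pool"), fingerprint$valid)
  if (index %in% pool$index) stop("Duplicate resample index in pool.", call. = FALSE)
  on_bound <- (is.finite(lower) & abs(optimum - lower) <= btol) |
    (is.finite(upper) & abs(optimum - upper) <= btol)
  pool$F <- rbind(pool$F, matrix(unname(fingerprint$values), 1))
  pool$Theta <- rbind(pool$Theta, matrix(unname(optimum), 1))
  pool$index <- c(pool$index, as.integer(index))
  pool$boundary <- rbind(pool$boundary, matrix(unname(on_bound), 1))
  pool
}

#' @export
print.training_pool <- function(x, ...) {
  cat("<training_pool>", nrow(x$F), "couples, fingerprint length",
      ncol(x$F), ", parameter dim", ncol(x$Theta), "\n")
  invisible(x)
}

pool_size <- function(pool) nrow(pool$F)

rbf_kernel <- function(X1, X2, width) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * X1 %*% t(X2)
  exp(-pmax(d2, 0) / (2 * width^2))
}

# ---------------------------------------------------------------------------
# LS-SVM regression = RBF kernel ridge with a constant offset feature.
# Training solves (K + J + lambda I) a = y  (J the all-ones matrix, i.e. a
# penalized intercept feature), prediction is f(x) = sum_i a_i (k(x, x_i)+1).
# For a linear smoother of this ridge form the leave-one-out residual has
# the closed form r_i / (1 - H_ii) with H = K'(K' + lambda I)^-1 — no
# explicit refits are needed to cross-validate.
# ---------------------------------------------------------------------------

#' Fit the fingerprint-to-optimum interpolator
#'
#' One multi-input single-output LS-SVM per parameter dimension. Fingerprint
#' components are standardized (mean 0, scale 1); the RBF width is selected
#' on a grid of `width_factors` times the median-heuristic width and the
#' ridge penalty on a logarithmic grid, both by exact leave-one-out mean
#' squared error. Couples whose optimum lies on a constraint in dimension
#' `k` are excluded from the model for dimension `k`; exact duplicate
#' couples are collapsed so predictions do not depend on how often a couple
#' was recorded.
#'
#' @param pool A [new_training_pool()] object.
#' @param lambda_grid Ridge penalties to try.
#' @param width_factors Multipliers of the median-heuristic kernel width.
#' @return An object of class `fp_interpolator` with elements `center`,
#'   `scale`, `models` (per dimension: standardized support points, kernel
#'   weights, width, lambda), `loo_error` (per-dimension RMS leave-one-out
#'   residual), `training_size`; or `NULL` if any dimension has fewer than
#'   two usable couples.
#' @export
fit_interpolator <- function(pool, lambda_grid = 10^seq(-6, 3),
                             width_factors = c(0.3, 1, 3)) {
  n <- pool_size(pool)
  d <- ncol(pool$Theta)
  if (n < 2) return(NULL)
  center <- colMeans(pool$F)
  scale <- apply(pool$F, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xall <- sweep(sweep(pool$F, 2, center), 2, scale, "/")

  models <- vector("list", d)
  loo_error <- numeric(d)
  for (k in seq_len(d)) {
    keep <- !pool$boundary[, k]
    X <- Xall[keep, , drop = FALSE]
    y <- pool$Theta[keep, k]
    dup <- duplicated(cbind(X, y))
    X <- X[!dup, , drop = FALSE]
    y <- y[!dup]
    if (length(y) < 2) return(NULL)
    fitk <- fit_lssvm_1d(X, y, lambda_grid, width_factors)
    models[[k]] <- fitk
    loo_error[k] <- fitk$loo_rmse
  }
  structure(list(center = center, scale = scale, models = models,
                 loo_error = loo_error, training_size = n),
            class = "fp_interpolator")
}

fit_lssvm_1d <- function(X, y, lambda_grid, width_factors) {
  n <- nrow(X)
  d2 <- as.numeric(stats::dist(X))
  w_med <- stats::median(d2)
  if (!is.finite(w_med) || w_med == 0) w_med <- 1
  best <- NULL
  for (wf in width_factors) {
    width <- wf * w_med
    Kp <- rbf_kernel(X, X, width) + 1
    eig <- eigen(Kp, symmetric = TRUE)
    Qty <- crossprod(eig$vectors, y)
    for (lambda in lambda_grid) {
      shrink <- eig$values / (eig$values + lambda)
      yhat <- eig$vectors %*% (shrink * Qty)
      hdiag <- rowSums(sweep(eig$vectors^2, 2, shrink, "*"))
      denom <- pmax(1 - hdiag, 1e-12)
      r_loo <- (y - yhat) / denom
      mse <- mean(r_loo^2)
      if (is.null(best) || mse < best$mse) {
        alpha <- eig$vectors %*% (Qty / (eig$values + lambda))
        best <- list(mse = mse, width = width, lambda = lambda,
                     alpha = as.numeric(alpha), X = X,
                     loo_rmse = sqrt(mse))
      }
    }
  }
  best
}

#' Closed-form leave-one-out residuals of a fitted per-dimension model
#'
#' Exposed mainly for verification: equals the residuals obtained by
#' explicitly refitting without each point in turn (same width and penalty).
#'
#' @param X Standardized input matrix.
#' @param y Output vector.
#' @param width,lambda Kernel width and ridge penalty.
#' @return Numeric vector of leave-one-out residuals `y_i - f_{-i}(x_i)`.
#' @export
lssvm_loo_residuals <- function(X, y, width, lambda) {
  Kp <- rbf_kernel(X, X, width) + 1
  H <- Kp %*% solve(Kp + diag(lambda, nrow(Kp)))
  (y - H %*% y) / (1 - diag(H))
}

#' Predict an optimum (with per-dimension uncertainty) from a fingerprint
#'
#' Raw per-dimension predictions are clipped to the box constraints: a
#' component violating its bound is set to the bound value. The
#' leave-one-out error `eps` of each dimension's model is returned alongside
#' as the prediction-uncertainty scale used to size the initial simplex.
#'
#' @param object A fitted `fp_interpolator`.
#' @param fingerprint A valid `fingerprint` of the training order.
#' @param lower,upper Box constraints (defaults: unconstrained).
#' @return List with `estimate` (clipped prediction vector) and `eps`
#'   (per-dimension leave-one-out RMS error).
#' @export
predict_optimum <- function(object, fingerprint,
                            lower = rep(-Inf, length(object$models)),
                            upper = rep(Inf, length(object$models))) {
  if (is.null(object)) stop("Interpolator is not fitted.", call. = FALSE)
  if (!fingerprint$valid) stop("Cannot predict from an invalid fingerprint.", call. = FALSE)
  x <- (fingerprint$values - object$center) / object$scale
  est <- vapply(object$models, function(m) {
    kx <- rbf_kernel(matrix(x, 1), m$X, m$width) + 1
    as.numeric(kx %*% m$alpha)
  }, numeric(1))
  est <- pmin(pmax(est, lower), upper)
  list(estimate = est, eps = object$loo_error)
}

#' @export
predict.fp_interpolator <- function(object, fingerprint, ...) {
  predict_optimum(object, fingerprint, ...)
}

#' Nearest-neighbor optimum prediction
#'
#' Returns the stored optimum of the pool couple whose fingerprint is
#' closest in squared Euclidean distance; ties go to the lowest original
#' resample index.
#'
#' @param pool A non-empty [new_training_pool()] object.
#' @param fingerprint A valid `fingerprint`.
#' @return Parameter vector of the nearest couple.
#' @export
nearest_neighbor_predict <- function(pool, fingerprint) {
  n <- pool_size(pool)
  if (n == 0) stop("Training pool is empty.", call. = FALSE)
  if (!fingerprint$valid) stop("Cannot predict from an invalid fingerprint.", call. = FALSE)
  dists <- colSums((t(pool$F) - fingerprint$values)^2)
  ord <- order(dists, pool$index)
  unname(pool$Theta[ord[1], ])
}
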