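#' Objective-model contract
#'
#' An `objective_model` bundles everything the resampling driver needs to
#' know about one estimation problem: a log-likelihood, the free-parameter
#' dimension, box constraints, a naive starting value, a nonparametric
#' resampler, and (where one exists) a closed-form optimum oracle.
#'
#' All built-in models phrase their objective as a *log-likelihood to be
#' maximized*; the optimizer negates it internally. `precompute()` may return
#' per-data-set cached quantities that `loglik()` accepts as its `cache`
#' argument, so that repeated evaluations on the same data set avoid
#' re-deriving sufficient statistics.
#'
#' @param name Identifier string.
#' @param dim Number of free parameters (positive integer).
#' @param loglik `function(theta, data, cache = NULL)` returning a scalar
#'   log-likelihood (`-Inf` allowed for invalid support).
#' @param lower,upper Numeric vectors of length `dim`; box constraints
#'   (`-Inf`/`Inf` for unconstrained dimensions).
#' @param naive_start `function(data)` returning a feasible parameter vector.
#' @param resample `function(data)` returning a resampled data set (uses the
#'   current RNG stream).
#' @param oracle Optional `function(data)` returning the exact optimum.
#' @param precompute Optional `function(data)` returning a cache object.
#' @param par_names Character vector of parameter labels (length `dim`).
#'
#' @return An object of class `objective_model`.
#' @export
objective_model <- function(name, dim, loglik, lower, upper, naive_start,
                            resample, oracle = NULL, precompute = NULL,
                            par_names = paste0("par", seq_len(dim))) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(dim), dim >= 1, dim == round(dim),
            is.function(loglik), is.function(naive_start),
            is.function(resample),
            length(lower) == dim, length(upper) == dim,
            all(lower <= upper), length(par_names) == dim)
  structure(
    list(name = name, dim = as.integer(dim), loglik = loglik,
         lower = as.numeric(lower), upper = as.numeric(upper),
         naive_start = naive_start, resample = resample, oracle = oracle,
         precompute = precompute, par_names = par_names),
    class = "objective_model"
  )
}

#' @export
print.objective_model <- function(x, ...) {
  cat("<objective_model> ", x$name, " (dim = ", x$dim, ")\n", sep = "")
  cat("  parameters:", paste(x$par_names, collapse = ", "), "\n")
  cat("  oracle:", if (is.null(x$oracle)) "none" else "closed form", "\n")
  invisible(x)
}

# Negated, constraint-aware objective bound to one data set. Infeasible
# parameters cost +Inf so the simplex retreats without special casing.
bind_objective <- function(model, data) {
  cache <- if (!is.null(model$precompute)) model$precompute(data) else NULL
  lower <- model$lower
  upper <- model$upper
  ll <- model$loglik
  function(theta) {
    if (any(theta < lower) || any(theta > upper)) return(Inf)
    v <- ll(theta, data, cache = cache)
    if (!is.finite(v)) Inf else -v
  }
}

# Positive log-likelihood closure (fingerprints differentiate this).
bind_loglik <- function(model, data) {
  cache <- if (!is.null(model$precompute)) model$precompute(data) else NULL
  ll <- model$loglik
  function(theta) ll(theta, data, cache = cache)
}

# ---------------------------------------------------------------------------
# Exponential distribution (mean parametrization)
# ---------------------------------------------------------------------------

#' Exponential log-likelihood (mean parametrization)
#'
#' `l(theta) = -n log(theta) - sum(x) / theta`, maximized at the sample mean.
#'
#' @param theta Mean parameter, strictly positive.
#' @param data Data frame with a numeric column `x` of nonnegative values.
#' @return Scalar log-likelihood.
#' @examples
#' exp_loglik(1, data.frame(x = c(1, 1)))  # -2
#' @export
exp_loglik <- function(theta, data) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("`theta` must be a single positive number.", call. = FALSE)
  }
  x <- data$x
  -length(x) * log(theta) - sum(x) / theta
}

#' Exponential objective model
#'
#' One-parameter exponential model in its mean parametrization, so the
#' maximum-likelihood estimate is the sample average (the closed-form
#' oracle). Rows are resampled i.i.d. with replacement.
#'
#' @return An [objective_model].
#' @export
model_exponential <- function() {
  objective_model(
    name = "exponential", dim = 1L,
    loglik = function(theta, data, cache = NULL) {
      if (theta[1] <= 0) return(-Inf)
      x <- data$x
      -length(x) * log(theta[1]) - sum(x) / theta[1]
    },
    lower = 0, upper = Inf,
    naive_start = function(data) 1,
    resample = function(data) data[sample.int(nrow(data), replace = TRUE), , drop = FALSE],
    oracle = function(data) mean(data$x),
    par_names = "theta"
  )
}

#' Simulate exponential data
#'
#' @param n Sample size.
#' @param mean Mean of the exponential distribution (default 2, the toy
#'   setting used throughout the package's examples).
#' @return A tibble with column `x`.
#' @export
simulate_exp_data <- function(n = 100, mean = 2) {
  stopifnot(n >= 1, mean > 0)
  tibble::tibble(x = stats::rexp(n, rate = 1 / mean))
}

# ---------------------------------------------------------------------------
# Linear regression without intercept, known unit error variance
# ---------------------------------------------------------------------------

#' No-intercept regression log-likelihood with unit error variance
#'
#' `l(beta) = -(n/2) log(2*pi) - 0.5 * sum((y - beta*x)^2)`, maximized at
#' `sum(x*y) / sum(x^2)`.
#'
#' @param beta Slope parameter.
#' @param data Data frame with numeric columns `x` and `y`.
#' @return Scalar log-likelihood.
#' @export
linreg_loglik <- function(beta, data) {
  if (sum(data$x^2) == 0) {
    stop("Degenerate design: sum(x^2) is zero.", call. = FALSE)
  }
  n <- nrow(data)
  -(n / 2) * log(2 * pi) - 0.5 * sum((data$y - beta[1] * data$x)^2)
}

#' No-intercept regression objective model
#'
#' Simple linear regression through the origin with known error variance 1.
#' The oracle optimum is `sum(x*y)/sum(x^2)`; rows (x, y pairs) are
#' resampled with replacement.
#'
#' @return An [objective_model].
#' @export
model_linreg <- function() {
  objective_model(
    name = "linreg", dim = 1L,
    loglik = function(theta, data, cache = NULL) {
      n <- nrow(data)
      -(n / 2) * log(2 * pi) - 0.5 * sum((data$y - theta[1] * data$x)^2)
    },
    lower = -Inf, upper = Inf,
    naive_start = function(data) 0,
    resample = function(data) data[sample.int(nrow(data), replace = TRUE), , drop = FALSE],
    oracle = function(data) sum(data$x * data$y) / sum(data$x^2),
    par_names = "beta"
  )
}

#' Simulate fixed-design regression data
#'
#' Design points are equally spaced on (0, 2]; responses are
#' `y = beta * x + e` with standard normal errors (the known-variance
#' setting of the regression toy).
#'
#' @param n Sample size.
#' @param beta True slope (default 2).
#' @return A tibble with columns `x`, `y`.
#' @export
simulate_linreg_data <- function(n = 100, beta = 2) {
  stopifnot(n >= 1)
  x <- 2 * seq_len(n) / n
  tibble::tibble(x = x, y = beta * x + stats::rnorm(n))
}

# ---------------------------------------------------------------------------
# Linear mixed model: random intercept + slope, profiled ML likelihood
# ---------------------------------------------------------------------------

# Per-cluster sufficient statistics for the profiled likelihood. The design
# is intercept + one predictor, identical for fixed and random effects, so
# Z_i = X_i and only Z'Z (2x2), Z'y (2), y'y and n_i are needed per cluster.
mixed_suffstats <- function(data) {
  stopifnot(all(c("cluster_id", "y", "x") %in% names(data)))
  split_idx <- split(seq_len(nrow(data)), data$cluster_id)
  stats_list <- lapply(split_idx, function(idx) {
    Z <- cbind(1, data$x[idx])
    y <- data$y[idx]
    list(ZtZ = crossprod(Z), Zty = crossprod(Z, y), yty = sum(y * y),
         n = length(idx))
  })
  list(clusters = stats_list, N = nrow(data))
}

# Core of the profiled ML computation. Gamma = L L' is the residual-scaled
# random-effects covariance. Uses Sylvester's determinant identity
# |Z Gamma Z' + I| = |I + Z'Z Gamma| and Woodbury for the quadratic forms,
# so each evaluation is O(#clusters).
mixed_profile_core <- function(chol3, cache) {
  L <- matrix(c(chol3[1], chol3[2], 0, chol3[3]), 2, 2)
  Gamma <- L %*% t(L)
  A <- matrix(0, 2, 2)   # sum Z' V*^-1 Z
  bvec <- c(0, 0)        # sum Z' V*^-1 y
  quad_y <- 0            # sum y' V*^-1 y
  logdet <- 0
  for (cl in cache$clusters) {
    M <- diag(2) + cl$ZtZ %*% Gamma
    d <- det(M)
    if (!is.finite(d) || d <= 0) return(NULL)
    logdet <- logdet + log(d)
    Minv <- solve(M)
    # V*^-1 = I - Z Gamma M^-1 Z'
    GM <- Gamma %*% Minv
    A <- A + cl$ZtZ - cl$ZtZ %*% GM %*% cl$ZtZ
    bvec <- bvec + cl$Zty - cl$ZtZ %*% GM %*% cl$Zty
    quad_y <- quad_y + cl$yty - crossprod(cl$Zty, GM %*% cl$Zty)
  }
  beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  rss <- as.numeric(quad_y - 2 * crossprod(beta, bvec) + crossprod(beta, A %*% beta))
  if (!is.finite(rss) || rss <= 0) return(NULL)
  N <- cache$N
  sigma2 <- rss / N
  nll <- 0.5 * (N * log(2 * pi) + logdet + N * log(sigma2) + N)
  list(negloglik = nll, beta = as.numeric(beta), sigma2 = sigma2,
       Gamma = Gamma)
}

#' Profiled negative log-likelihood of the random-intercept-and-slope model
#'
#' The linear mixed model `y_ij = b0 + b1 x_ij + u_{0i} + u_{1i} x_ij + e_ij`
#' with `(u_{0i}, u_{1i}) ~ N(0, D)` and `e_ij ~ N(0, sigma^2)` is fitted by
#' maximum likelihood after two reparametrizations: the residual-scaled
#' random-effects covariance `Gamma = D / sigma^2` is written as `L L'` with
#' `L` lower triangular (3 free entries, guaranteeing positive
#' semidefiniteness), and the fixed effects and `sigma^2` are profiled out in
#' closed form (GLS and the ML variance estimator). The optimization problem
#' is therefore three-dimensional.
#'
#' @param chol Numeric length-3 vector `(L11, L21, L22)` of the free
#'   Cholesky entries. Signs are unconstrained; the likelihood depends on
#'   `L L'` only.
#' @param data Data frame with columns `cluster_id`, `y`, `x` (the
#'   within-cluster predictor, e.g. a lagged response).
#' @return Scalar negative profiled log-likelihood (`Inf` on numerical
#'   failure such as a singular marginal covariance).
#' @seealso [mixed_recover()] to translate an optimum back to
#'   `(beta, sigma2, D)`.
#' @export
mixed_profiled_negloglik <- function(chol, data) {
  stopifnot(length(chol) == 3)
  core <- mixed_profile_core(chol, mixed_suffstats(data))
  if (is.null(core)) return(Inf)
  core$negloglik
}

#' Recover natural mixed-model parameters from a profiled optimum
#'
#' @inheritParams mixed_profiled_negloglik
#' @return A list with `beta` (fixed effects, length 2), `sigma2` (residual
#'   variance), and `D` (2x2 random-effects covariance `sigma2 * L L'`,
#'   symmetric positive semidefinite).
#' @export
mixed_recover <- function(chol, data) {
  core <- mixed_profile_core(chol, mixed_suffstats(data))
  if (is.null(core)) stop("Profiled likelihood undefined at this point.", call. = FALSE)
  D <- core$sigma2 * core$Gamma
  dimnames(D) <- list(c("intercept", "slope"), c("intercept", "slope"))
  list(beta = core$beta, sigma2 = core$sigma2, D = D)
}

#' Mixed-model objective model (profiled, 3 free parameters)
#'
#' Objective model wrapper around [mixed_profiled_negloglik()]: the
#' log-likelihood is the *negated* profiled deviance so that, like every
#' model in the package, it is maximized. Resampling is the case bootstrap:
#' whole clusters are drawn with replacement and relabeled `1..N` so that a
#' cluster drawn twice enters as two distinct units.
#'
#' @return An [objective_model] with `dim = 3`.
#' @export
model_mixed <- function() {
  objective_model(
    name = "mixed", dim = 3L,
    loglik = function(theta, data, cache = NULL) {
      if (is.null(cache)) cache <- mixed_suffstats(data)
      core <- mixed_profile_core(theta, cache)
      if (is.null(core)) return(-Inf)
      -core$negloglik
    },
    lower = rep(-Inf, 3), upper = rep(Inf, 3),
    naive_start = function(data) c(0.1, 0, 0.1),
    resample = function(data) case_bootstrap(data),
    oracle = NULL,
    precompute = mixed_suffstats,
    par_names = c("L11", "L21", "L22")
  )
}

#' Case bootstrap for clustered data
#'
#' Draws clusters (not rows) with replacement, keeping the number of
#' clusters fixed, and relabels cluster ids `1..N` so repeated draws of the
#' same cluster are treated as distinct units.
#'
#' @param data Data frame with a `cluster_id` column.
#' @return A tibble with the same columns; `cluster_id` relabeled.
#' @export
case_bootstrap <- function(data) {
  ids <- unique(data$cluster_id)
  drawn <- sample(ids, length(ids), replace = TRUE)
  idx <- split(seq_len(nrow(data)), data$cluster_id)
  pieces <- lapply(seq_along(drawn), function(k) {
    piece <- data[idx[[as.character(drawn[k])]], , drop = FALSE]
    piece$cluster_id <- k
    piece
  })
  dplyr::bind_rows(pieces)
}

#' Simulate unbalanced clustered longitudinal data
#'
#' Emulates an experience-sampling-style design: each cluster (subject)
#' contributes a random number of observations, the predictor is a
#' standardized within-cluster series (as a lagged response would be), and
#' both intercept and slope carry correlated normal random effects.
#'
#' @param n_clusters Number of clusters (default 30).
#' @param size_range Integer range of per-cluster sizes, drawn uniformly
#'   (default 40 to 100, i.e. unbalanced).
#' @param beta Fixed effects `(intercept, slope)`.
#' @param sigma2 Residual variance.
#' @param D 2x2 random-effects covariance (intercept, slope).
#' @return A tibble with columns `cluster_id`, `x`, `y`.
#' @export
simulate_mixed_data <- function(n_clusters = 30, size_range = c(40, 100),
                                beta = c(1, 0.3), sigma2 = 1,
                                D = matrix(c(0.4, 0.1, 0.1, 0.2), 2, 2)) {
  stopifnot(n_clusters >= 1, sigma2 > 0, nrow(D) == 2, ncol(D) == 2)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("`D` must be positive semidefinite.", call. = FALSE)
  Dhalf <- chol_psd(D)
  sizes <- sample(seq(size_range[1], size_range[2]), n_clusters, replace = TRUE)
  pieces <- lapply(seq_len(n_clusters), function(i) {
    m <- sizes[i]
    b <- as.numeric(Dhalf %*% stats::rnorm(2))
    x <- stats::rnorm(m)
    y <- (beta[1] + b[1]) + (beta[2] + b[2]) * x + stats::rnorm(m, sd = sqrt(sigma2))
    tibble::tibble(cluster_id = i, x = x, y = y)
  })
  dplyr::bind_rows(pieces)
}

# Lower-triangular square root tolerating semidefinite D.
chol_psd <- function(D) {
  e <- eigen(D, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(D)) %*% t(e$vectors)
}

# ---------------------------------------------------------------------------
# Generalized extreme value distribution, location linear in a covariate
# ---------------------------------------------------------------------------

GEV_GUMBEL_EPS <- 1e-8

#' GEV negative log-likelihood with location drifting in a covariate
#'
#' Block-maxima likelihood with location `mu_i = alpha + beta * t_i`, scale
#' `sigma` and shape `xi` (a four-dimensional problem). The density is
#' defined only where `1 + xi * (x - mu) / sigma > 0` for every observation;
#' outside that support the function returns `Inf` carrying attribute
#' `support_violation = TRUE` so an optimizer can retreat instead of
#' crashing. For `|xi|` below 1e-8 the Gumbel limit formulas are used.
#'
#' @param params Numeric length-4 vector `(xi, sigma, alpha, beta)`.
#' @param data Data frame with columns `x` (block maximum) and `t`
#'   (covariate, e.g. date of measurement).
#' @return Scalar negative log-likelihood, possibly `Inf`.
#' @export
gev_negloglik <- function(params, data) {
  xi <- params[1]; sigma <- params[2]; alpha <- params[3]; beta <- params[4]
  if (!is.finite(sigma) || sigma <= 0) return(Inf)
  z <- (data$x - alpha - beta * data$t) / sigma
  n <- length(z)
  if (abs(xi) < GEV_GUMBEL_EPS) {
    return(n * log(sigma) + sum(z) + sum(exp(-z)))
  }
  u <- 1 + xi * z
  if (any(u <= 0)) {
    return(structure(Inf, support_violation = TRUE))
  }
  n * log(sigma) + (1 + 1 / xi) * sum(log(u)) + sum(u^(-1 / xi))
}

#' Naive GEV starting values
#'
#' Location trend `(alpha, beta)` from the simple regression of `x` on `t`;
#' scale from the residual standard deviation through the Gumbel moment
#' relation `sd = sigma * pi / sqrt(6)`; shape started at 0.1 (moment-style
#' starting values in the spirit of probability-weighted-moment estimators).
#' If the support condition fails at the start, the scale is inflated until
#' it holds.
#'
#' @param data Data frame with columns `x`, `t`.
#' @return Numeric length-4 vector `(xi, sigma, alpha, beta)`.
#' @export
gev_naive_start <- function(data) {
  stopifnot(nrow(data) >= 3)
  fit <- stats::lm(x ~ t, data = data)
  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  s <- stats::sd(stats::resid(fit))
  if (!is.finite(s) || s == 0) {
    stop("Degenerate data: zero residual variance.", call. = FALSE)
  }
  sigma <- s * sqrt(6) / pi
  xi <- 0.1
  start <- c(xi, sigma, alpha, beta)
  for (k in 1:100) {
    v <- gev_negloglik(start, data)
    if (is.finite(v)) break
    start[2] <- start[2] * 1.5
  }
  start
}

#' GEV objective model (shape, scale, location intercept and slope)
#'
#' @return An [objective_model] with `dim = 4`; `sigma` is bounded below by
#'   zero, all other parameters are free. Resampling draws `(x, t)` rows
#'   with replacement.
#' @export
model_gev <- function() {
  objective_model(
    name = "gev", dim = 4L,
    loglik = function(theta, data, cache = NULL) {
      v <- gev_negloglik(theta, data)
      if (!is.finite(v)) return(-Inf)
      -v
    },
    lower = c(-Inf, 0, -Inf, -Inf), upper = rep(Inf, 4),
    naive_start = function(data) gev_naive_start(data),
    resample = function(data) data[sample.int(nrow(data), replace = TRUE), , drop = FALSE],
    oracle = NULL,
    par_names = c("xi", "sigma", "alpha", "beta")
  )
}

#' Simulate block maxima from a nonstationary GEV
#'
#' Inverts the GEV distribution function: `x = mu + sigma * ((-log U)^(-xi)
#' - 1) / xi` (Gumbel limit for `xi = 0`), with `mu_i = alpha + beta * t_i`
#' and `t` equally spaced on `t_range`. Defaults emulate a century-scale
#' daily-maximum windspeed record in arbitrary units.
#'
#' @param n Sample size.
#' @param xi,sigma,alpha,beta GEV parameters; `sigma > 0`.
#' @param t_range Covariate range (default `c(0, 1)`).
#' @return A tibble with columns `x`, `t`.
#' @export
simulate_gev_data <- function(n = 500, xi = 0.1, sigma = 1, alpha = 10,
                              beta = 0.5, t_range = c(0, 1)) {
  stopifnot(n >= 1, sigma > 0)
  t <- seq(t_range[1], t_range[2], length.out = n)
  u <- stats::runif(n)
  mu <- alpha + beta * t
  x <- if (abs(xi) < GEV_GUMBEL_EPS) {
    mu - sigma * log(-log(u))
  } else {
    mu + sigma * ((-log(u))^(-xi) - 1) / xi
  }
  tibble::tibble(x = x, t = t)
}

#' Built-in model registry
#'
#' @param name One of `"exponential"`, `"linreg"`, `"mixed"`, `"gev"`.
#' @return The corresponding [objective_model].
#' @export
get_model <- function(name) {
  switch(match.arg(name, c("exponential", "linreg", "mixed", "gev")),
         exponential = model_exponential(),
         linreg = model_linreg(),
         mixed = model_mixed(),
         gev = model_gev())
}
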