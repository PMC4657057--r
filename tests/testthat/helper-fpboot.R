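# Shared fixtures and independent oracles, built in code at test time.

# Full (unprofiled) marginal likelihood of the random-intercept-and-slope
# model; independent oracle for the profiled implementation.
# par = (beta1, beta2, sigma2, D11, D12, D22)
full_mixed_negloglik <- function(par, data) {
  beta <- par[1:2]; sigma2 <- par[3]
  D <- matrix(c(par[4], par[5], par[5], par[6]), 2, 2)
  if (!is.finite(sigma2) || sigma2 <= 0) return(Inf)
  if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values < 0)) return(Inf)
  nll <- 0
  for (cl in split(data, data$cluster_id)) {
    Z <- cbind(1, cl$x)
    r <- cl$y - Z %*% beta
    V <- Z %*% D %*% t(Z) + diag(sigma2, nrow(Z))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    nll <- nll + 0.5 * (nrow(Z) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          sum(backsolve(ch, r, transpose = TRUE)^2))
  }
  as.numeric(nll)
}

# Central-difference Hessian of a scalar function (for standard errors).
num_hessian <- function(f, x, h = 1e-4 * (1 + abs(x))) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
  }
  if (d > 1) {
    for (i in seq_len(d - 1)) for (j in (i + 1):d) {
      pp <- x; pp[i] <- pp[i] + h[i]; pp[j] <- pp[j] + h[j]
      pm <- x; pm[i] <- pm[i] + h[i]; pm[j] <- pm[j] - h[j]
      mp <- x; mp[i] <- mp[i] - h[i]; mp[j] <- mp[j] + h[j]
      mm <- x; mm[i] <- mm[i] - h[i]; mm[j] <- mm[j] - h[j]
      H[i, j] <- H[j, i] <- (f(pp) - f(pm) - f(mp) + f(mm)) / (4 * h[i] * h[j])
    }
  }
  H
}

# Wrap a model so every log-likelihood evaluation increments a counter.
counting_model <- function(model) {
  env <- new.env()
  env$n <- 0L
  ll <- model$loglik
  model$loglik <- function(theta, data, cache = NULL) {
    env$n <- env$n + 1L
    ll(theta, data, cache = cache)
  }
  list(model = model, counter = env)
}

# Small mixed-model fixture used by several tests.
small_mixed_data <- function(seed = 42, n_clusters = 5, m = 8) {
  set.seed(seed)
  simulate_mixed_data(n_clusters = n_clusters, size_range = c(m, m),
                      beta = c(1, 0.5), sigma2 = 1,
                      D = matrix(c(0.5, 0.1, 0.1, 0.3), 2, 2))
}

# Build a training pool from resamples using a closed-form oracle for the
# optima (no optimizer involved), for interpolator learning tests.
oracle_pool <- function(model, data, theta0, n, g = 1) {
  fp_len <- if (g == 1) model$dim else model$dim + model$dim * (model$dim + 1) / 2
  pool <- new_training_pool(fp_len, model$dim)
  for (b in seq_len(n)) {
    rs <- model$resample(data)
    fp <- compute_fingerprint(model, rs, theta0, g = g)
    pool <- pool_add(pool, fp, model$oracle(rs), b, model$lower, model$upper)
  }
  pool
}
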