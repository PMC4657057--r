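test_that("exponential log-likelihood matches closed form and its oracle", {
  expect_equal(exp_loglik(1, data.frame(x = c(1, 1))), -2)
  expect_equal(exp_loglik(2, data.frame(x = 2)), -log(2) - 1)
  expect_error(exp_loglik(-1, data.frame(x = 1)), "positive")

  m <- model_exponential()
  d <- data.frame(x = c(1, 3))
  expect_equal(m$oracle(d), 2)
  fit <- fit_model(m, d)
  expect_equal(fit$optimum, 2, tolerance = 1e-4)
})

test_that("regression log-likelihood matches closed form and its oracle", {
  expect_equal(linreg_loglik(1, data.frame(x = 1, y = 1)), -0.5 * log(2 * pi))
  expect_equal(linreg_loglik(0, data.frame(x = 1, y = 1)),
               -0.5 * log(2 * pi) - 0.5)
  expect_error(linreg_loglik(1, data.frame(x = 0, y = 1)), "[Dd]egenerate")

  m <- model_linreg()
  d <- data.frame(x = c(1, 2), y = c(2, 4))
  expect_equal(m$oracle(d), 2)
  fit <- fit_model(m, d)
  expect_equal(fit$optimum, 2, tolerance = 1e-4)
})

test_that("closed-form oracles maximize their log-likelihoods", {
  set.seed(1)
  for (spec in list(list(m = model_exponential(), gen = function() simulate_exp_data(30)),
                    list(m = model_linreg(), gen = function() simulate_linreg_data(30)))) {
    for (rep in 1:50) {
      d <- spec$gen()
      opt <- spec$m$oracle(d)
      l0 <- spec$m$loglik(opt, d)
      for (delta in c(-1e-3, 1e-3)) {
        expect_lte(spec$m$loglik(opt + delta, d), l0)
      }
    }
  }
})

test_that("profiled mixed likelihood collapses to OLS when Gamma = 0", {
  d <- small_mixed_data()
  fit <- stats::lm(y ~ x, data = d)
  n <- nrow(d)
  s2 <- mean(stats::resid(fit)^2)
  ols_nll <- 0.5 * (n * log(2 * pi) + n * log(s2) + n)
  expect_equal(mixed_profiled_negloglik(c(0, 0, 0), d), ols_nll, tolerance = 1e-10)
})

test_that("profiled likelihood is invariant to the Cholesky sign symmetry", {
  d <- small_mixed_data()
  for (c3 in list(c(0.5, 0.2, 0.3), c(1, -0.4, 0.2))) {
    expect_equal(mixed_profiled_negloglik(c3, d),
                 mixed_profiled_negloglik(-c3, d), tolerance = 1e-12)
  }
})

test_that("profiled optimum agrees with a brute-force full-likelihood fit", {
  d <- small_mixed_data()
  prof <- fit_model(model_mixed(), d, tol_x = 1e-8, tol_f = 1e-8)
  rec <- mixed_recover(prof$optimum, d)

  # The full likelihood at the recovered parameters must reproduce the
  # profiled value exactly (profiling identity).
  par_prof <- c(rec$beta, rec$sigma2, rec$D[1, 1], rec$D[1, 2], rec$D[2, 2])
  expect_equal(full_mixed_negloglik(par_prof, d), prof$value, tolerance = 1e-8)

  # A direct joint optimization of the 6-parameter likelihood (in an
  # unconstrained log-variance / Cholesky parametrization, so the simplex
  # never hits the positive-definiteness wall) finds the same optimum.
  to_natural <- function(u) {
    C <- matrix(c(u[4], u[5], 0, u[6]), 2, 2)
    D <- C %*% t(C)
    c(u[1], u[2], exp(u[3]), D[1, 1], D[1, 2], D[2, 2])
  }
  f_free <- function(u) full_mixed_negloglik(to_natural(u), d)
  c11 <- sqrt(rec$D[1, 1]); c21 <- rec$D[1, 2] / c11
  c22 <- sqrt(max(rec$D[2, 2] - c21^2, 1e-12))
  u0 <- c(rec$beta, log(rec$sigma2), c11, c21, c22) * 1.1 + 0.01
  full <- list(par = u0)
  for (k in 1:4) {
    full <- stats::optim(full$par, f_free, method = "Nelder-Mead",
                         control = list(maxit = 20000, reltol = 1e-15))
  }
  expect_equal(full$value, prof$value, tolerance = 1e-6)
  expect_equal(to_natural(full$par), par_prof, tolerance = 1e-3)
})

test_that("mixed parameter recovery translates Cholesky optima back to D", {
  d <- small_mixed_data()
  expect_equal(unname(mixed_recover(c(0, 0, 0), d)$D), matrix(0, 2, 2))
  rec <- mixed_recover(c(1, 0, 1), d)
  expect_equal(unname(rec$D), rec$sigma2 * diag(2), tolerance = 1e-12)
  ev <- eigen(mixed_recover(c(0.7, -0.3, 0.4), d)$D, only.values = TRUE)$values
  expect_true(all(ev >= -1e-12))
})

test_that("GEV likelihood honours the support condition and the Gumbel limit", {
  expect_true(is.infinite(gev_negloglik(c(1, 1, 0, 0), data.frame(x = -1.5, t = 0))))
  expect_true(attr(gev_negloglik(c(1, 1, 0, 0), data.frame(x = -1.5, t = 0)),
                   "support_violation"))
  # Gumbel density at its location is exp(-1).
  expect_equal(gev_negloglik(c(0, 1, 0, 0), data.frame(x = 0, t = 0)), 1)
  # Continuity at the shape boundary.
  set.seed(3)
  d <- simulate_gev_data(50, xi = 0)
  for (xi in c(1e-10, -1e-10)) {
    expect_equal(gev_negloglik(c(xi, 1, 10, 0.5), d),
                 gev_negloglik(c(0, 1, 10, 0.5), d), tolerance = 1e-6)
  }
  # Location invariance: shifting x and alpha together changes nothing.
  v1 <- gev_negloglik(c(0.2, 1.3, 10, 0.5), d)
  d2 <- d; d2$x <- d2$x + 5
  expect_equal(gev_negloglik(c(0.2, 1.3, 15, 0.5), d2), v1, tolerance = 1e-10)
})

test_that("GEV naive start is feasible and tracks the data", {
  set.seed(4)
  d <- simulate_gev_data(200, xi = 0, sigma = 1, alpha = 10, beta = 2)
  st <- gev_naive_start(d)
  expect_true(is.finite(gev_negloglik(st, d)))
  expect_gt(st[2], 0)
  expect_true(st[1] >= -0.5 && st[1] <= 0.5)
  fit <- stats::lm(x ~ t, data = d)
  expect_equal(st[3:4], unname(stats::coef(fit)))
  # Constant shift moves alpha only.
  d2 <- d; d2$x <- d2$x + 7
  st2 <- gev_naive_start(d2)
  expect_equal(st2[3], st[3] + 7, tolerance = 1e-10)
  expect_equal(st2[c(1, 2, 4)], st[c(1, 2, 4)], tolerance = 1e-10)
})

test_that("resamplers keep shapes and respect the case-bootstrap contract", {
  # One-row data set: resample is that row repeated.
  m <- model_exponential()
  one <- data.frame(x = 3.3)
  expect_equal(m$resample(one)$x, 3.3)

  # Case bootstrap: cluster count preserved, ids relabeled, within-cluster
  # rows kept as intact multisets.
  d <- small_mixed_data(seed = 7, n_clusters = 3, m = 4)
  set.seed(1)
  rs <- case_bootstrap(d)
  expect_equal(sort(unique(rs$cluster_id)), 1:3)
  orig_blocks <- lapply(split(d[c("x", "y")], d$cluster_id),
                        function(b) b[order(b$x), ])
  for (cl in split(rs[c("x", "y")], rs$cluster_id)) {
    cl <- cl[order(cl$x), ]
    match_found <- any(vapply(orig_blocks, function(b) {
      nrow(b) == nrow(cl) && isTRUE(all.equal(b$x, cl$x)) &&
        isTRUE(all.equal(b$y, cl$y))
    }, logical(1)))
    expect_true(match_found)
  }

  # Fixed seed gives identical resamples.
  set.seed(99); a <- m$resample(data.frame(x = 1:10))
  set.seed(99); b <- m$resample(data.frame(x = 1:10))
  expect_identical(a, b)
})

test_that("synthetic generators hit their nominal regimes", {
  set.seed(10)
  d <- simulate_exp_data(100, mean = 2)
  expect_lt(abs(mean(d$x) - 2), 2 * 2 / sqrt(100))

  # Mixed generator with D = 0: per-cluster OLS residual variance near 1.
  set.seed(11)
  dm <- simulate_mixed_data(n_clusters = 40, size_range = c(50, 50),
                            sigma2 = 1, D = matrix(0, 2, 2))
  rv <- vapply(split(dm, dm$cluster_id), function(cl) {
    mean(stats::resid(stats::lm(y ~ x, data = cl))^2)
  }, numeric(1))
  expect_lt(abs(mean(rv) - 1), 0.1)

  expect_error(simulate_mixed_data(sigma2 = -1), "sigma2")
  expect_error(simulate_mixed_data(D = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive semidefinite")
})

test_that("parameter dimensions are 1, 1, 3 and 4", {
  expect_equal(model_exponential()$dim, 1L)
  expect_equal(model_linreg()$dim, 1L)
  expect_equal(model_mixed()$dim, 3L)
  expect_equal(model_gev()$dim, 4L)
})
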