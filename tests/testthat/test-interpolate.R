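test_that("interpolator learns the exact affine relation of the exponential toy", {
  m <- model_exponential()
  set.seed(31)
  d <- simulate_exp_data(100, 2)
  theta0 <- m$oracle(d)
  pool <- oracle_pool(m, d, theta0, n = 15)
  interp <- fit_interpolator(pool)
  expect_s3_class(interp, "fp_interpolator")
  spread <- diff(range(pool$Theta[, 1]))
  errs <- vapply(1:30, function(i) {
    rs <- m$resample(d)
    fp <- compute_fingerprint(m, rs, theta0, g = 1)
    # In-range queries only: extrapolation is handled by the driver's
    # prioritized initial phase, not by the interpolator.
    if (fp$values < min(pool$F) || fp$values > max(pool$F)) return(NA_real_)
    abs(predict_optimum(interp, fp, m$lower, m$upper)$estimate - m$oracle(rs))
  }, numeric(1))
  expect_lt(mean(errs, na.rm = TRUE), 1e-3 * spread)
})

test_that("closed-form leave-one-out residuals equal explicit refits", {
  set.seed(32)
  n <- 12
  X <- matrix(rnorm(n * 2), n, 2)
  y <- X[, 1]^2 + 0.5 * X[, 2] + rnorm(n, sd = 0.1)
  for (lambda in c(1e-3, 1)) {
    width <- 1.5
    closed <- lssvm_loo_residuals(X, y, width, lambda)
    brute <- vapply(seq_len(n), function(i) {
      Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
      Kp <- exp(-as.matrix(dist(Xi))^2 / (2 * width^2)) + 1
      alpha <- solve(Kp + diag(lambda, n - 1), yi)
      kx <- exp(-colSums((t(Xi) - X[i, ])^2) / (2 * width^2)) + 1
      y[i] - sum(kx * alpha)
    }, numeric(1))
    expect_equal(as.numeric(closed), brute, tolerance = 1e-8)
  }
})

test_that("duplicated couples do not change predictions", {
  m <- model_exponential()
  set.seed(33)
  d <- simulate_exp_data(60, 2)
  theta0 <- m$oracle(d)
  pool <- oracle_pool(m, d, theta0, n = 12)
  pool2 <- pool
  # Re-add couple 1 under a new index.
  fp1 <- structure(list(values = pool$F[1, ], order = 1L, eval_cost = 2L,
                        valid = TRUE), class = "fingerprint")
  pool2 <- pool_add(pool2, fp1, pool$Theta[1, ], 999L, m$lower, m$upper)
  i1 <- fit_interpolator(pool)
  i2 <- fit_interpolator(pool2)
  rs <- m$resample(d)
  fp <- compute_fingerprint(m, rs, theta0, g = 1)
  p1 <- predict_optimum(i1, fp, m$lower, m$upper)$estimate
  p2 <- predict_optimum(i2, fp, m$lower, m$upper)$estimate
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("predictions are clipped to the constraints", {
  # A pool whose outputs straddle zero, constraint theta >= 0.
  pool <- new_training_pool(1, 1)
  mk <- function(v) structure(list(values = v, order = 1L, eval_cost = 2L,
                                   valid = TRUE), class = "fingerprint")
  set.seed(34)
  xs <- seq(-2, 2, length.out = 12)
  for (i in seq_along(xs)) {
    pool <- pool_add(pool, mk(xs[i]), xs[i], i, lower = -Inf, upper = Inf)
  }
  interp <- fit_interpolator(pool)
  pred_free <- predict_optimum(interp, mk(-1.5))$estimate
  expect_lt(pred_free, 0)
  pred_clip <- predict_optimum(interp, mk(-1.5), lower = 0, upper = Inf)$estimate
  expect_identical(pred_clip, 0)
  # Unconstrained: raw prediction returned unchanged.
  expect_equal(predict_optimum(interp, mk(0.7))$estimate, 0.7, tolerance = 0.05)
})

test_that("optima on a constraint boundary are excluded from training", {
  pool <- new_training_pool(1, 1)
  mk <- function(v) structure(list(values = v, order = 1L, eval_cost = 2L,
                                   valid = TRUE), class = "fingerprint")
  # Interior couples on an affine relation plus boundary couples pinned at 0.
  for (i in 1:10) pool <- pool_add(pool, mk(i), i, i, lower = 0, upper = Inf)
  for (i in 11:14) pool <- pool_add(pool, mk(-i), 0, i, lower = 0, upper = Inf)
  expect_equal(sum(pool$boundary), 4)
  interp <- fit_interpolator(pool)
  # The affine interior relation is learned despite the pinned couples.
  expect_equal(predict_optimum(interp, mk(5.5))$estimate, 5.5, tolerance = 0.2)
})

test_that("fitting signals when fewer than two usable couples exist", {
  pool <- new_training_pool(1, 1)
  expect_null(fit_interpolator(pool))
  mk <- function(v) structure(list(values = v, order = 1L, eval_cost = 2L,
                                   valid = TRUE), class = "fingerprint")
  pool <- pool_add(pool, mk(1), 1, 1L, -Inf, Inf)
  expect_null(fit_interpolator(pool))
})

test_that("nearest-neighbor prediction honours distances and the tie rule", {
  mk <- function(v) structure(list(values = v, order = 1L, eval_cost = 2L,
                                   valid = TRUE), class = "fingerprint")
  pool <- new_training_pool(2, 1)
  pool <- pool_add(pool, mk(c(0, 0)), 10, 1L, -Inf, Inf)
  expect_equal(nearest_neighbor_predict(pool, mk(c(5, 5))), 10)
  pool <- pool_add(pool, mk(c(1, 1)), 20, 2L, -Inf, Inf)
  expect_equal(nearest_neighbor_predict(pool, mk(c(1, 1))), 20)
  # Equidistant query: lower original index wins.
  expect_equal(nearest_neighbor_predict(pool, mk(c(0.5, 0.5))), 10)
  empty <- new_training_pool(2, 1)
  expect_error(nearest_neighbor_predict(empty, mk(c(0, 0))), "empty")
})

test_that("predictions are invariant to affine rescaling of fingerprint components", {
  set.seed(35)
  mk <- function(v) structure(list(values = v, order = 1L, eval_cost = 4L,
                                   valid = TRUE), class = "fingerprint")
  n <- 25
  F1 <- cbind(rnorm(n), rnorm(n))
  y <- 2 * F1[, 1] - F1[, 2] + rnorm(n, sd = 0.05)
  scale_map <- function(Fm) cbind(100 * Fm[, 1] + 7, -0.01 * Fm[, 2])
  p1 <- new_training_pool(2, 1); p2 <- new_training_pool(2, 1)
  F2 <- scale_map(F1)
  for (i in seq_len(n)) {
    p1 <- pool_add(p1, mk(F1[i, ]), y[i], i, -Inf, Inf)
    p2 <- pool_add(p2, mk(F2[i, ]), y[i], i, -Inf, Inf)
  }
  i1 <- fit_interpolator(p1); i2 <- fit_interpolator(p2)
  for (q in 1:5) {
    v <- rnorm(2) * 0.5
    a <- predict_optimum(i1, mk(v))$estimate
    b <- predict_optimum(i2, mk(as.numeric(scale_map(matrix(v, 1)))))$estimate
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("prediction error shrinks with training size on the exponential toy", {
  m <- model_exponential()
  med_err <- function(size) {
    errs <- vapply(1:20, function(seed) {
      set.seed(400 + seed)
      d <- simulate_exp_data(100, 2)
      theta0 <- m$oracle(d)
      pool <- oracle_pool(m, d, theta0, n = size)
      interp <- fit_interpolator(pool)
      mean(vapply(1:20, function(i) {
        rs <- m$resample(d)
        fp <- compute_fingerprint(m, rs, theta0, g = 1)
        abs(predict_optimum(interp, fp, m$lower, m$upper)$estimate - m$oracle(rs))
      }, numeric(1)))
    }, numeric(1))
    stats::median(errs)
  }
  e5 <- med_err(5); e20 <- med_err(20); e80 <- med_err(80)
  expect_lt(e20, e5)
  expect_lt(e80, e20)
})
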