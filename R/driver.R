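#' Plan a fingerprint-resampling run
#'
#' A plan fixes the variant (which starting-value option is used), the
#' fingerprint order, the bypass ratio and the resampling budget.
#' `bypass` with `p = 0` is identical to `warm_start` (predictions are used
#' as starting values but every resample is still optimized).
#'
#' @param option One of `"naive"` (model's naive start for every resample),
#'   `"original_optimum"` (original fit as start), `"warm_start"`
#'   (interpolator prediction as start), `"bypass"` (prediction used
#'   directly as the estimate for `p` resamples per optimized one).
#' @param g Fingerprint derivative order (1 or 2); used by the fingerprint
#'   variants only.
#' @param p Bypass ratio, nonnegative; used by `"bypass"` only.
#' @param B Total number of resamples (the estimate budget).
#' @param n_random_initial Number of randomly chosen resamples added to the
#'   extrapolation-avoiding initial phase (default 20).
#' @return An object of class `fpr_plan`.
#' @export
fpr_plan <- function(option = c("original_optimum", "naive", "warm_start", "bypass"),
                     g = 1, p = 0, B = 200, n_random_initial = 20) {
  option <- match.arg(option)
  stopifnot(g %in% c(1, 2), p >= 0, B >= 1, n_random_initial >= 0)
  structure(list(option = option, g = as.integer(g), p = p, B = as.integer(B),
                 n_random_initial = as.integer(n_random_initial)),
            class = "fpr_plan")
}

#' @export
print.fpr_plan <- function(x, ...) {
  cat("<fpr_plan>", x$option,
      if (x$option %in% c("warm_start", "bypass")) paste0("(g = ", x$g, ")") else "",
      if (x$option == "bypass") paste0("p = ", x$p) else "",
      " B =", x$B, "\n")
  invisible(x)
}

#' Fit the original data set
#'
#' Full Nelder-Mead fit from the model's naive start. The resulting original
#' optimum is the expansion point for all fingerprints and the default warm
#' start; its cost is not charged to the resampling budget because it is
#' computed before (and independently of) the resampling process.
#'
#' @inheritParams fit_model
#' @return List with `theta0`, `value`, `n_evals`, `converged`.
#' @export
fit_original <- function(model, data, tol_x = 1e-6, tol_f = 1e-6) {
  res <- fit_model(model, data, tol_x = tol_x, tol_f = tol_f)
  if (!res$converged) stop("Original fit did not converge.", call. = FALSE)
  list(theta0 = res$optimum, value = res$value, n_evals = res$n_evals,
       converged = res$converged)
}

#' Extrapolation-avoiding processing order
#'
#' Given the fingerprints of all resamples, prioritizes the resamples whose
#' fingerprints attain the per-dimension minima and maxima (deduplicated),
#' adds `n_random` further resamples drawn uniformly at random, and leaves
#' the rest in original index order. Solving the prioritized resamples first
#' keeps later predictions inside the trained fingerprint range.
#'
#' @param fingerprints List of `fingerprint` objects (invalid ones are never
#'   prioritized).
#' @param n_random Number of random additions to the initial phase.
#' @return List with `prioritized` (initial-phase indices, extremes first)
#'   and `remaining` (all other indices in increasing order).
#' @export
initial_phase_order <- function(fingerprints, n_random = 20) {
  B <- length(fingerprints)
  valid <- which(vapply(fingerprints, function(f) f$valid, logical(1)))
  extremes <- integer(0)
  if (length(valid) > 0) {
    Fm <- do.call(rbind, lapply(fingerprints[valid], function(f) f$values))
    for (j in seq_len(ncol(Fm))) {
      extremes <- c(extremes, valid[which.min(Fm[, j])], valid[which.max(Fm[, j])])
    }
    extremes <- unique(extremes)
  }
  rest <- setdiff(seq_len(B), extremes)
  n_random <- min(n_random, length(rest))
  randoms <- if (n_random > 0) sort(sample(rest, n_random)) else integer(0)
  prioritized <- c(extremes, randoms)
  list(prioritized = prioritized,
       remaining = setdiff(seq_len(B), prioritized))
}

#' Predicted-estimate allowance of the bypass variant
#'
#' With bypass ratio `p`, each optimizer-based estimate licenses `p`
#' predicted estimates, but the total number of estimates never exceeds the
#' budget `B`.
#'
#' @param n_optimized Number of optimizer-based estimates so far.
#' @param p Bypass ratio.
#' @param B Total estimate budget.
#' @return List with `n_predicted` (predicted estimates added) and
#'   `n_total` (total estimates).
#' @examples
#' bypass_allowance(200, p = 3, B = 2000)   # 600 predicted, 800 total
#' bypass_allowance(1800, p = 3, B = 2000)  # capped at 200 predicted
#' @export
bypass_allowance <- function(n_optimized, p, B) {
  n_pred <- min(p * n_optimized, B - n_optimized)
  list(n_predicted = n_pred, n_total = n_optimized + n_pred)
}

#' Run a fingerprint-resampling bootstrap
#'
#' Orchestrates one full run: fits the original optimum, draws all `B`
#' resamples, and processes them according to the plan. For the fingerprint
#' variants, the fingerprints of all resamples are computed up front (their
#' evaluation cost is charged to the budget), extreme-fingerprint resamples
#' are solved first from the original optimum, and thereafter the
#' learned fingerprint-to-optimum relation supplies warm starts
#' (`warm_start`) or final estimates (`bypass`, `p` predicted per optimized
#' estimate). The interpolator is refit when the pool has grown by
#' `max(refit_min, refit_frac * training_size)` couples since the last fit,
#' and refitting stops once the pool exceeds `pool_cap` couples.
#'
#' All randomness descends from `seed` through separate child streams for
#' resampling and initial-phase selection, so runs with different options
#' but the same seed see identical resamples.
#'
#' @param data Original data set (data frame).
#' @param model An [objective_model].
#' @param plan An [fpr_plan()].
#' @param seed Integer root seed.
#' @param tol_x,tol_f Nelder-Mead tolerances.
#' @param cores Batch size for the parallel-execution replay: records within
#'   a batch of `cores` consecutive estimates can only use couples from
#'   earlier batches. `cores = 1` is the fully serial run.
#' @param step_scale Fingerprint finite-difference step scale.
#' @param refit_min,refit_frac,pool_cap Interpolator refit cadence.
#' @return An object of class `fpr_run`: list with `records` (one row per
#'   estimate, in processing order), `theta0`, `original_fit`, `model`,
#'   `plan`, `seed`, `cores`, `refit_log`.
#' @export
fpr_run <- function(data, model, plan, seed = 1, tol_x = 1e-6, tol_f = 1e-6,
                    cores = 1, step_scale = 1e-4,
                    refit_min = 10, refit_frac = 0.1, pool_cap = 1000) {
  stopifnot(inherits(model, "objective_model"), inherits(plan, "fpr_plan"),
            cores >= 1)
  set.seed(as.integer(seed))
  child <- sample.int(.Machine$integer.max - 1L, 2)  # resampling / phase streams

  original <- fit_original(model, data, tol_x = tol_x, tol_f = tol_f)
  theta0 <- original$theta0
  B <- plan$B
  d <- model$dim

  set.seed(child[1])
  resamples <- purrr::map(seq_len(B), function(b) model$resample(data))

  state <- list(rows = vector("list", B), n_rows = 0L)
  emit <- function(state, index, start, estimate, n_evals, fp_cost,
                   bypassed, prioritized, converged) {
    state$n_rows <- state$n_rows + 1L
    row <- c(list(step = state$n_rows, index = index, bypassed = bypassed,
                  prioritized = prioritized, n_evals = n_evals,
                  fingerprint_cost = fp_cost, weight = 1,
                  converged = converged),
             stats::setNames(as.list(estimate), paste0("estimate_", model$par_names)),
             stats::setNames(as.list(start), paste0("start_", model$par_names)))
    state$rows[[state$n_rows]] <- tibble::as_tibble(row)
    state
  }
  optimize_one <- function(index, start, eps = NULL) {
    fit_model(model, resamples[[index]], start = start, eps = eps,
              tol_x = tol_x, tol_f = tol_f)
  }

  if (plan$option %in% c("naive", "original_optimum")) {
    for (b in seq_len(B)) {
      start <- if (plan$option == "naive") model$naive_start(resamples[[b]]) else theta0
      res <- optimize_one(b, start)
      state <- emit(state, b, start, res$optimum, res$n_evals, 0L,
                    bypassed = FALSE, prioritized = FALSE,
                    converged = res$converged)
    }
    records <- dplyr::bind_rows(state$rows)
    return(new_fpr_run(records, original, model, plan, seed, cores,
                       refit_log = tibble::tibble()))
  }

  # Fingerprint variants: compute all fingerprints up front.
  fps <- purrr::map(resamples, function(rs)
    compute_fingerprint(model, rs, theta0, g = plan$g, step_scale = step_scale))
  set.seed(child[2])
  ord <- initial_phase_order(fps, plan$n_random_initial)
  queue <- c(ord$prioritized, ord$remaining)
  is_initial <- c(rep(TRUE, length(ord$prioritized)),
                  rep(FALSE, length(ord$remaining)))

  fp_len <- if (plan$g == 1) d else d + d * (d + 1) / 2
  pool <- new_training_pool(fp_len, d)
  interp <- NULL
  last_fit_size <- 0L
  refit_log <- list()
  # Batch replay: couples only become visible at batch boundaries.
  visible_upto <- 0L          # pool rows usable by the interpolator

  maybe_refit <- function() {
    avail <- visible_upto
    if (avail < 2) return(invisible())
    if (avail > pool_cap && !is.null(interp)) return(invisible())
    due <- avail - last_fit_size >= max(refit_min, refit_frac * last_fit_size)
    if (is.null(interp) || due) {
      vis_pool <- pool
      vis_pool$F <- pool$F[seq_len(avail), , drop = FALSE]
      vis_pool$Theta <- pool$Theta[seq_len(avail), , drop = FALSE]
      vis_pool$index <- pool$index[seq_len(avail)]
      vis_pool$boundary <- pool$boundary[seq_len(avail), , drop = FALSE]
      fitted <- fit_interpolator(vis_pool)
      if (!is.null(fitted)) {
        interp <<- fitted
        last_fit_size <<- avail
        refit_log[[length(refit_log) + 1L]] <<- tibble::tibble(
          training_size = fitted$training_size,
          eps = list(fitted$loo_error))
      }
    }
    invisible()
  }
  close_batch_if_needed <- function() {
    if (state$n_rows %% cores == 0L) {
      visible_upto <<- pool_size(pool)
      maybe_refit()
    }
  }

  qpos <- 1L
  n_queue <- length(queue)
  while (qpos <= n_queue && state$n_rows < B) {
    b <- queue[qpos]
    initial <- is_initial[qpos]
    qpos <- qpos + 1L
    fp <- fps[[b]]
    fp_cost <- fp$eval_cost

    if (initial || is.null(interp) || !fp$valid) {
      # Initial phase / fallback: optimize from the original optimum
      # (naive start if the fingerprint is invalid at theta0).
      start <- if (fp$valid) theta0 else model$naive_start(resamples[[b]])
      res <- optimize_one(b, start)
      state <- emit(state, b, start, res$optimum, res$n_evals, fp_cost,
                    bypassed = FALSE, prioritized = initial,
                    converged = res$converged)
      if (fp$valid) {
        pool <- pool_add(pool, fp, res$optimum, b, model$lower, model$upper)
      }
      close_batch_if_needed()
      next
    }

    # Learned phase: predict, then warm-start optimize. A prediction can
    # land in an infeasible region (e.g. GEV support); fall back to the
    # original optimum in that case.
    pred <- predict_optimum(interp, fp, model$lower, model$upper)
    res <- tryCatch(optimize_one(b, pred$estimate, eps = pred$eps),
                    error = function(e) NULL)
    start_used <- pred$estimate
    if (is.null(res)) {
      start_used <- theta0
      res <- optimize_one(b, theta0)
    }
    state <- emit(state, b, start_used, res$optimum, res$n_evals, fp_cost,
                  bypassed = FALSE, prioritized = FALSE,
                  converged = res$converged)
    pool <- pool_add(pool, fp, res$optimum, b, model$lower, model$upper)
    close_batch_if_needed()

    # Bypass: p predicted estimates per optimized one, within budget.
    if (plan$option == "bypass" && plan$p > 0) {
      n_byp <- min(plan$p, n_queue - qpos + 1L)
      while (n_byp > 0 && qpos <= n_queue && state$n_rows < B) {
        b2 <- queue[qpos]
        qpos <- qpos + 1L
        n_byp <- n_byp - 1L
        fp2 <- fps[[b2]]
        if (!fp2$valid) {
          start <- model$naive_start(resamples[[b2]])
          res2 <- optimize_one(b2, start)
          state <- emit(state, b2, start, res2$optimum, res2$n_evals,
                        fp2$eval_cost, bypassed = FALSE, prioritized = FALSE,
                        converged = res2$converged)
        } else {
          pred2 <- predict_optimum(interp, fp2, model$lower, model$upper)
          state <- emit(state, b2, pred2$estimate, pred2$estimate, 0L,
                        fp2$eval_cost, bypassed = TRUE, prioritized = FALSE,
                        converged = NA)
        }
        close_batch_if_needed()
      }
    }
  }

  records <- dplyr::bind_rows(state$rows)
  new_fpr_run(records, original, model, plan, seed, cores,
              refit_log = if (length(refit_log)) dplyr::bind_rows(refit_log)
                          else tibble::tibble())
}

new_fpr_run <- function(records, original, model, plan, seed, cores,
                        refit_log) {
  structure(list(records = records, theta0 = original$theta0,
                 original_fit = original, model = model, plan = plan,
                 seed = seed, cores = cores, refit_log = refit_log),
            class = "fpr_run")
}

#' Regenerate the resampled data sets of a run
#'
#' Resamples are not stored in the run object; they are reproduced from the
#' run's seed (the resampling child stream is derived deterministically).
#'
#' @param run An `fpr_run`.
#' @param data The original data set the run was produced from.
#' @return List of `B` resampled data sets, indexed by original resample
#'   index.
#' @export
run_resamples <- function(run, data) {
  set.seed(as.integer(run$seed))
  child <- sample.int(.Machine$integer.max - 1L, 2)
  set.seed(child[1])
  lapply(seq_len(run$plan$B), function(b) run$model$resample(data))
}

#' @export
print.fpr_run <- function(x, ...) {
  cat("<fpr_run> model:", x$model$name, " option:", x$plan$option,
      " B:", nrow(x$records), "\n")
  cat("  original optimum:", format(x$theta0, digits = 5), "\n")
  cat("  total cost:", total_cost(x$records), "function evaluations",
      "(", sum(x$records$bypassed), "bypassed )\n")
  invisible(x)
}

#' Total function-evaluation cost of a run
#'
#' Computation time is expressed hardware-independently as the number of
#' objective-function evaluations: optimizer evaluations plus the
#' finite-difference cost of the fingerprints. Interpolator algebra is not
#' counted (it does not scale with the difficulty of one objective
#' evaluation).
#'
#' @param records An `fpr_run` or its records tibble.
#' @return Integer total.
#' @export
total_cost <- function(records) {
  if (inherits(records, "fpr_run")) records <- records$records
  as.integer(sum(records$n_evals) + sum(records$fingerprint_cost))
}

#' Write run records to CSV
#'
#' One row per estimate in processing order; columns `step`, `index`,
#' `bypassed`, `prioritized`, `n_evals`, `fingerprint_cost`, `weight`,
#' `converged`, and the estimate and start components. Identical seeds give
#' byte-identical files.
#'
#' @param run An `fpr_run`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(run, path) {
  readr::write_csv(run$records, path)
  invisible(path)
}
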