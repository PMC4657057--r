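#' Percentile-bootstrap estimate (floored order statistic)
#'
#' The `alpha` percentile of `B` bootstrap estimates is the ascending order
#' statistic of rank `max(1, floor(alpha * B))`. With weights the same
#' flooring convention applies in weight units: the largest value whose
#' normalized cumulative weight does not exceed `alpha` (floored at the
#' smallest estimate), which reduces exactly to the unweighted rule when all
#' weights are equal.
#'
#' @param estimates Numeric vector of bootstrap estimates.
#' @param alpha Percentile level in (0, 1) (default 0.025, the lower bound
#'   of a 95% interval).
#' @param weights Optional nonnegative weights, same length as `estimates`.
#' @return Scalar percentile estimate.
#' @examples
#' percentile_estimate(seq(10, 2000, by = 10), alpha = 0.025)  # 50
#' @export
percentile_estimate <- function(estimates, alpha = 0.025, weights = NULL) {
  if (length(estimates) == 0) stop("`estimates` is empty.", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  ord <- order(estimates)
  sorted <- estimates[ord]
  if (is.null(weights)) {
    r <- max(1L, floor(alpha * length(sorted)))
    return(sorted[r])
  }
  stopifnot(length(weights) == length(estimates), all(weights >= 0),
            sum(weights) > 0)
  cw <- cumsum(weights[ord]) / sum(weights)
  r <- max(1L, sum(cw <= alpha))
  sorted[r]
}

#' Bootstrap bias estimate
#'
#' Componentwise mean of the bootstrap optima minus the original optimum.
#' Under zero estimated bias the original optimum is exactly the mean of the
#' bootstrap optima, which is why it makes a good default starting value.
#'
#' @param estimates Numeric vector or matrix (rows = resamples).
#' @param theta0 Original optimum (scalar or vector).
#' @return Numeric bias vector.
#' @export
bootstrap_bias <- function(estimates, theta0) {
  m <- if (is.matrix(estimates)) colMeans(estimates) else mean(estimates)
  m - theta0
}

#' Extract per-record estimates of one statistic from a run
#'
#' For most models this is a single estimate column. For the mixed model the
#' statistics of interest are the recovered random-effects (co)variances
#' (`sD11`, `sD12`, `sD22` of `D = sigma2 * L L'`), which are invariant to
#' the sign symmetry of the Cholesky parameters; pass `data` to recover them
#' per record.
#'
#' @param run An `fpr_run`.
#' @param parameter Parameter label: one of the model's `par_names`, or for
#'   the mixed model `"sD11"`, `"sD12"`, `"sD22"`.
#' @param data Original data set; required for mixed-model recovery, where
#'   each record's resample is regenerated (see [run_resamples()]) and the
#'   record's Cholesky estimate is translated back to `D` on that resample.
#' @return Numeric vector, one value per record in processing order.
#' @export
record_estimates <- function(run, parameter, data = NULL) {
  recs <- run$records
  direct <- paste0("estimate_", parameter)
  if (direct %in% names(recs)) return(recs[[direct]])
  if (run$model$name == "mixed" && parameter %in% c("sD11", "sD12", "sD22")) {
    if (is.null(data)) stop("`data` is required to recover mixed-model variances.",
                            call. = FALSE)
    resamples <- run_resamples(run, data)
    ch <- as.matrix(recs[, paste0("estimate_", run$model$par_names)])
    vals <- vapply(seq_len(nrow(recs)), function(i) {
      rec <- mixed_recover(ch[i, ], resamples[[recs$index[i]]])
      switch(parameter, sD11 = rec$D[1, 1], sD12 = rec$D[1, 2],
             sD22 = rec$D[2, 2])
    }, numeric(1))
    return(vals)
  }
  stop("Unknown parameter `", parameter, "`.", call. = FALSE)
}

#' Reference percentile from a large pooled set of estimates
#'
#' The speed-accuracy curves score percentile estimates against a reference
#' computed from strictly more estimates than any curve uses. For models
#' with a closed-form oracle the pooled optima are computed exactly from
#' `n_pool` fresh resamples; otherwise the optima of `n_runs` independent
#' original-optimum runs are pooled.
#'
#' @param data Original data set.
#' @param model An [objective_model] (oracle required unless `n_runs`
#'   runs are affordable).
#' @param alpha Percentile level.
#' @param n_pool Number of pooled resamples when an oracle exists.
#' @param n_runs,B Number and size of pooled runs when optimizing.
#' @param seed Seed for the pooling resamples.
#' @param parameter Parameter label pooled when runs are used (see
#'   [record_estimates()]).
#' @return List with `value` (reference percentile) and `n` (pool size).
#' @export
reference_percentile <- function(data, model, alpha = 0.025, n_pool = 20000,
                                 n_runs = 10, B = 200, seed = 1,
                                 parameter = model$par_names[1]) {
  set.seed(seed)
  if (!is.null(model$oracle)) {
    ests <- vapply(seq_len(n_pool), function(i) model$oracle(model$resample(data)),
                   numeric(1))
    return(list(value = percentile_estimate(ests, alpha), n = n_pool))
  }
  plan <- fpr_plan("original_optimum", B = B)
  ests <- unlist(lapply(seq_len(n_runs), function(r) {
    run <- fpr_run(data, model, plan, seed = seed + r)
    record_estimates(run, parameter, data = data)
  }))
  list(value = percentile_estimate(ests, alpha), n = length(ests))
}

#' Speed-accuracy trade-off curve
#'
#' For each prefix of the run's estimates (in processing order) the weighted
#' percentile estimate is compared with the reference; the error
#' `delta = |qhat_b - q_ref|` is paired with the cumulative
#' function-evaluation cost up to that estimate. Fingerprint costs are
#' charged up front (all fingerprints are computed before any estimate is
#' produced). Prioritized (out-of-order) estimates are down-weighted at
#' prefix length `b` by `min(1, b / original_index)`, so the weighting has
#' no effect once all estimates are used.
#'
#' @param run An `fpr_run`.
#' @param parameter Parameter label (see [record_estimates()]).
#' @param reference Reference percentile value (see [reference_percentile()]).
#' @param alpha Percentile level.
#' @param data Original data (for mixed-model recovery).
#' @return A tibble of class `fpr_accuracy_curve` with columns
#'   `n_estimates`, `cum_cost`, `delta`.
#' @export
accuracy_curve <- function(run, parameter, reference, alpha = 0.025,
                           data = NULL) {
  recs <- run$records
  vals <- record_estimates(run, parameter, data = data)
  B <- nrow(recs)
  fp_total <- sum(recs$fingerprint_cost)
  cost <- fp_total + cumsum(recs$n_evals)
  delta <- vapply(seq_len(B), function(b) {
    w <- pmin(1, b / recs$index[seq_len(b)])
    abs(percentile_estimate(vals[seq_len(b)], alpha, weights = w) - reference)
  }, numeric(1))
  out <- tibble::tibble(n_estimates = seq_len(B), cum_cost = cost,
                        delta = delta)
  class(out) <- c("fpr_accuracy_curve", class(out))
  attr(out, "parameter") <- parameter
  attr(out, "variant") <- paste0(run$plan$option,
                                 if (run$plan$option %in% c("warm_start", "bypass"))
                                   paste0("_g", run$plan$g) else "",
                                 if (run$plan$option == "bypass")
                                   paste0("_p", run$plan$p) else "")
  out
}

#' Cost to first reach an accuracy level
#'
#' @param curve An [accuracy_curve()] tibble.
#' @param threshold Error threshold.
#' @return Cumulative cost at the first record whose error is at or below
#'   `threshold`, or `NA` if never reached.
#' @export
cost_to_accuracy <- function(curve, threshold) {
  hit <- which(curve$delta <= threshold)
  if (length(hit) == 0) return(NA_real_)
  curve$cum_cost[hit[1]]
}

#' Speed-up of a variant over a baseline at a fixed accuracy
#'
#' The high-accuracy level is approximately the lowest error the baseline
#' (original optimum) curve achieves (with 5% slack, since all variants
#' share the same Monte-Carlo error floor and an exact minimum is reached
#' only by the curve that defines it); the medium level doubles the
#' baseline's lowest error. The speed-up is the ratio of baseline cost to
#' variant cost at the first crossing of the level.
#'
#' @param curve_variant,curve_baseline [accuracy_curve()] tibbles on the
#'   same parameter and reference.
#' @param level `"high"`, `"medium"`, or a numeric error threshold.
#' @return Positive speed-up factor.
#' @export
speedup_at_accuracy <- function(curve_variant, curve_baseline,
                                level = c("high", "medium")) {
  thr <- if (is.numeric(level)) level else {
    base_err <- min(curve_baseline$delta)
    switch(match.arg(level), high = 1.05 * base_err, medium = 2 * base_err)
  }
  c_base <- cost_to_accuracy(curve_baseline, thr)
  c_var <- cost_to_accuracy(curve_variant, thr)
  if (is.na(c_base) || is.na(c_var)) {
    stop("Accuracy level never reached; speed-up undefined.", call. = FALSE)
  }
  c_base / c_var
}

#' Replay a run as if executed on C parallel cores
#'
#' Estimates are grouped in batches of `cores`; estimates in the same batch
#' cannot learn from each other, only from earlier batches. The run is
#' recomputed under that information constraint with the stored plan, model,
#' data and seed. `cores = 1` reproduces the serial run exactly; with
#' `cores >= B` nothing can be learned (warm starts degrade to the original
#' optimum) while fingerprint costs are still incurred.
#'
#' @param run An `fpr_run`.
#' @param data The original data set the run was produced from.
#' @param cores Batch size (number of parallel workers).
#' @return A new `fpr_run` under the batch constraint.
#' @export
parallel_replay <- function(run, data, cores) {
  fpr_run(data, run$model, run$plan, seed = run$seed, cores = cores)
}
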