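#' Fitts's-law throughput
#'
#' Information throughput of successful trials:
#' `sum_k log2(1 + (D_k - S) / (2 S)) / t_acq` bits per second, where `D_k`
#' is the k-th finger's centre-to-target distance at target onset, `S` the
#' target radius (`target_width / 2`) and `t_acq` the acquisition time in
#' seconds. Unsuccessful and excluded trials are omitted.
#'
#' @param trials trial-record data frame (needs `d1, d2,
#'   target_onset_bin, end_bin, success`).
#' @param task a [task_config()].
#' @return list with `per_trial` (bits/s), `mean`, `sem`, `n`.
#' @export
#' @examples
#' tr <- data.frame(trial = 1, target1 = 0, target2 = 0, start_bin = 1,
#'                  target_onset_bin = 1, acquire_bin = 11, end_bin = 20,
#'                  success = TRUE, d1 = 0.375, d2 = 0.075, excluded = FALSE)
#' fitts_throughput(tr, task_config())$per_trial  # log2(3) ~ 1.585
fitts_throughput <- function(trials, task) {
  S <- task$target_width / 2
  ok <- trials$success & !isTRUE_or_col(trials$excluded)
  tr <- trials[ok, , drop = FALSE]
  t_acq <- (tr$end_bin - tr$target_onset_bin + 1) * task$bin_size / 1000
  if (any(t_acq <= 0)) stop("invalid trial record: nonpositive t_acq")
  bits <- log2(1 + pmax(tr$d1 - S, 0) / (2 * S)) +
    log2(1 + pmax(tr$d2 - S, 0) / (2 * S))
  tp <- bits / t_acq
  list(per_trial = tp, mean = mean(tp),
       sem = stats::sd(tp) / sqrt(length(tp)), n = length(tp))
}

isTRUE_or_col <- function(x) if (is.null(x)) FALSE else x

#' Trial timing metrics
#'
#' Splits each successful trial's acquisition time into time-to-target
#' (target onset to the start of the final continuous in-target hold) and
#' dwell time (that final hold), recomputed from the position series
#' against the targets. `acquisition = time_to_target + dwell` by
#' construction.
#'
#' @param trials trial-record data frame.
#' @param session the `session_bundle` covering the trials.
#' @param task a [task_config()].
#' @param first_entry report time-to-target at the first target entry
#'   instead of the final-hold start.
#' @return data frame of per-trial metrics (ms) plus success flags.
#' @export
trial_times <- function(trials, session, task, first_entry = FALSE) {
  kin <- session$kin
  w2 <- task$target_width / 2
  bs <- task$bin_size
  out <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    idx <- tr$start_bin:tr$end_bin
    inside <- abs(kin$p1[idx] - tr$target1) <= w2 &
      abs(kin$p2[idx] - tr$target2) <= w2
    acq <- (tr$end_bin - tr$target_onset_bin + 1) * bs
    if (!tr$success) {
      return(data.frame(trial = tr$trial, success = FALSE,
                        acquisition_time = acq,
                        time_to_target = NA_real_, dwell_time = NA_real_))
    }
    runs <- rle(inside)
    last_run <- length(runs$values)
    stopifnot(runs$values[last_run])  # success ends inside the targets
    dwell_bins <- runs$lengths[last_run]
    entry_bin <- if (first_entry) {
      idx[which(inside)[1]]
    } else {
      idx[length(idx) - dwell_bins + 1L]
    }
    ttt <- (entry_bin - tr$target_onset_bin) * bs
    data.frame(trial = tr$trial, success = TRUE, acquisition_time = acq,
               time_to_target = ttt, dwell_time = acq - ttt)
  })
  do.call(rbind, out)
}

#' Pearson correlation between predicted and actual velocities
#'
#' @param pred data frame or matrix with per-finger predicted velocities.
#' @param actual matching actual velocities.
#' @return list with `per_finger` correlations and their `mean`.
#' @export
velocity_correlation <- function(pred, actual) {
  P <- as.matrix(if (is.data.frame(pred)) pred[, c("v1", "v2")] else pred)
  A <- as.matrix(if (is.data.frame(actual)) actual[, c("v1", "v2")] else actual)
  stopifnot(nrow(P) == nrow(A))
  r <- vapply(seq_len(ncol(P)), function(f) {
    if (stats::sd(P[, f]) == 0 || stats::sd(A[, f]) == 0)
      stop("undefined correlation: constant series")
    stats::cor(P[, f], A[, f])
  }, numeric(1))
  list(per_finger = r, mean = mean(r))
}

#' Trial-aligned mean speed profile
#'
#' Aligns successful trials at target onset and averages the two-finger
#' mean speed over the first `window_ms`. Trials completed before the
#' window ends contribute zero velocity from completion to the window end.
#'
#' @param session a `session_bundle`.
#' @param task a [task_config()].
#' @param window_ms analysis window after target onset (default 2000).
#' @return list with `time_ms`, `mean`, `sem`, `peak` and `time_to_peak_ms`.
#' @export
mean_speed_profile <- function(session, task, window_ms = 2000) {
  kin <- session$kin
  bs <- task$bin_size
  nb <- as.integer(window_ms / bs)
  tr <- session$trials[session$trials$success, , drop = FALSE]
  if (nrow(tr) == 0) stop("no successful trials")
  speed <- (abs(kin$v1) + abs(kin$v2)) / 2
  M <- matrix(0, nrow(tr), nb)
  for (i in seq_len(nrow(tr))) {
    span <- tr$target_onset_bin[i]:min(tr$end_bin[i],
                                       tr$target_onset_bin[i] + nb - 1L)
    M[i, seq_along(span)] <- speed[span]
  }
  mu <- colMeans(M)
  sem <- apply(M, 2, stats::sd) / sqrt(nrow(M))
  list(time_ms = seq_len(nb) * bs - bs / 2, mean = mu, sem = sem,
       peak = max(mu), time_to_peak_ms = (which.max(mu)) * bs - bs / 2)
}

#' Predicted-speed curve over binned true speed
#'
#' Bins the magnitude of the true velocity (in units of its standard
#' deviation) into bins of size 1.0 at intervals of 0.5, and averages the
#' magnitude of the predicted velocity in each bin. Predictions are first
#' rescaled so that their standard deviation within the near-zero true-
#' velocity bin (|true| < `zero_frac` sigma) equals 0.5, putting decoders
#' with different output scales on a common axis.
#'
#' @param pred predicted velocities (data frame with `v1, v2` or matrix).
#' @param actual actual velocities, same shape.
#' @param zero_frac width of the near-zero normalization bin in sigma units
#'   (default 0.25).
#' @param max_sigma largest bin centre, in sigma units (default 4).
#' @return a `velocity_curve`: data frame `center, mean_pred, sem_pred, n`.
#' @export
binned_velocity_curve <- function(pred, actual, zero_frac = 0.25,
                                  max_sigma = 4) {
  P <- as.matrix(if (is.data.frame(pred)) pred[, c("v1", "v2")] else pred)
  A <- as.matrix(if (is.data.frame(actual)) actual[, c("v1", "v2")] else actual)
  sig <- apply(A, 2, stats::sd)
  anorm <- c(abs(sweep(A, 2, sig, `/`)))
  pv <- c(P)
  zero <- anorm < zero_frac
  if (!any(zero)) stop("empty zero bin: cannot normalize predictions")
  sd0 <- stats::sd(pv[zero])
  if (sd0 == 0) stop("zero-variance predictions in the zero bin")
  pnorm <- abs(pv) * (0.5 / sd0)
  centers <- seq(0, max_sigma, by = 0.5)
  rows <- lapply(centers, function(cc) {
    in_bin <- anorm >= cc - 0.5 & anorm < cc + 0.5
    n <- sum(in_bin)
    if (n == 0) return(NULL)
    data.frame(center = cc, mean_pred = mean(pnorm[in_bin]),
               sem_pred = stats::sd(pnorm[in_bin]) / sqrt(n), n = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("velocity_curve", "data.frame")
  out
}

#' One- and two-sample t-tests
#'
#' Thin wrapper over [stats::t.test()]: one-sample two-tailed against a
#' hypothesized mean, or two-sample two-sided with pooled (equal) variance.
#'
#' @param a numeric sample.
#' @param b second sample (two-sample) or hypothesized mean (one-sample).
#' @param kind `"one_sample"` or `"two_sample"`.
#' @return list with `t`, `p`, `df`.
#' @export
t_tests <- function(a, b, kind = c("one_sample", "two_sample")) {
  kind <- match.arg(kind)
  if (length(a) < 2) stop("need at least 2 observations per sample")
  ht <- if (kind == "one_sample") {
    stopifnot(length(b) == 1)
    stats::t.test(a, mu = b, alternative = "two.sided")
  } else {
    if (length(b) < 2) stop("need at least 2 observations per sample")
    stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  }
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}
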