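#' Simulate open-loop (manipulandum-control) user kinematics
#'
#' Runs the intention-driven user on the random-target two-finger task in
#' open loop: the displayed fingers follow the user's own intended velocity,
#' so every trial succeeds. Targets span the configured placement range,
#' satisfy the separation rule, and each trial ends after a continuous
#' `hold_time_train` hold inside both targets.
#'
#' @param task a [task_config()].
#' @param n_trials number of trials (>= 1).
#' @param seed integer session seed.
#' @param user a [user_config()].
#' @return a list with `kin` (data frame `bin, p1, p2, v1, v2`) and
#'   `trials` (one row per trial: targets, timing bins, success flag,
#'   initial centre-to-target distances `d1, d2`).
#' @export
#' @examples
#' out <- simulate_user_kinematics(task_config(), n_trials = 3, seed = 7)
#' out$trials
simulate_user_kinematics <- function(task, n_trials, seed,
                                     user = user_config()) {
  res <- simulate_loop(NULL, NULL, task, user, n_trials, seed,
                       mode = "manipulandum")
  list(kin = res$kin, trials = res$trials)
}

#' Bundle a session
#'
#' The universal interchange object: binned SBP, kinematics, trial records
#' and metadata. In `manipulandum` mode `kin` holds the true (user) finger
#' kinematics; in `brain_control` mode it holds the decoded kinematics and
#' `kin_intended` the user's intended kinematics.
#'
#' @param sbp an `sbp_matrix` (channels x bins).
#' @param kin kinematics data frame (`bin, p1, p2, v1, v2`).
#' @param trials trial-record data frame.
#' @param mode `"manipulandum"` or `"brain_control"`.
#' @param meta named list of metadata (seed, descriptions, ...).
#' @param kin_intended optional intended kinematics (brain-control runs).
#' @return an object of class `session_bundle`.
#' @export
session_bundle <- function(sbp, kin, trials,
                           mode = c("manipulandum", "brain_control"),
                           meta = list(), kin_intended = NULL) {
  mode <- match.arg(mode)
  if (!is.null(sbp) && ncol(sbp) != nrow(kin))
    stop("SBP and kinematics must cover the same bins")
  if (nrow(trials) > 0 && max(trials$end_bin) > nrow(kin))
    stop("trial bin ranges must lie within the session length")
  structure(list(sbp = sbp, kin = kin, trials = trials, mode = mode,
                 meta = meta, kin_intended = kin_intended),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("Session bundle (%s): %d bins, %d trials (%d successful)",
              x$mode, nrow(x$kin), nrow(x$trials), sum(x$trials$success)))
  if (!is.null(x$sbp)) cat(sprintf(", %d channels", nrow(x$sbp)))
  cat("\n")
  if (!is.null(x$meta$seed)) cat(sprintf("  seed: %s\n", x$meta$seed))
  invisible(x)
}

#' @export
summary.session_bundle <- function(object, ...) {
  tr <- object$trials
  dt <- (object$kin$bin[2] - object$kin$bin[1])
  cat(sprintf("%s session: %d trials, %.1f%% successful, %d bins\n",
              object$mode, nrow(tr), 100 * mean(tr$success), nrow(object$kin)))
  v <- c(object$kin$v1, object$kin$v2)
  cat(sprintf("  velocity sd %.3f u/s, speed range [0, %.2f] u/s\n",
              stats::sd(v), max(abs(v))))
  invisible(object)
}

#' Generate a full synthetic training session
#'
#' Composes the open-loop user simulation with the synthetic encoder: runs
#' `n_trials` manipulandum-control trials and encodes the resulting
#' kinematics into SBP bin-by-bin. A 500-trial call supports the standard
#' 400-trial training / 100-trial validation split made by the caller (see
#' [split_session()]).
#'
#' @param task a [task_config()].
#' @param enc an [make_encoder()] model.
#' @param n_trials number of trials.
#' @param seed integer session seed (drives targets, user jitter and
#'   encoder noise through named streams).
#' @param user a [user_config()].
#' @return a `session_bundle` with `mode = "manipulandum"`.
#' @export
generate_session <- function(task, enc, n_trials, seed,
                             user = user_config()) {
  stopifnot(inherits(enc, "encoder_model"))
  res <- simulate_loop(NULL, enc, task, user, n_trials, seed,
                       mode = "manipulandum")
  session_bundle(res$sbp, res$kin, res$trials, mode = "manipulandum",
                 meta = list(seed = seed,
                             encoder = sprintf(
                               "synthetic %d-ch mix=%.2f lag=%d noise=%.2f",
                               enc$n_channels, enc$nonlinearity_mix,
                               enc$lag_bins, enc$noise_scale)))
}

#' Split a session into leading/trailing trial blocks
#'
#' Cuts a session at a trial boundary, e.g. 400 training trials followed by
#' 100 validation trials.
#'
#' @param session a `session_bundle`.
#' @param n_train number of leading trials for the first block.
#' @return list of two `session_bundle`s, `train` and `val`.
#' @export
split_session <- function(session, n_train) {
  tr <- session$trials
  stopifnot(n_train >= 1, n_train < nrow(tr))
  cut <- tr$end_bin[n_train]
  idx1 <- seq_len(cut)
  idx2 <- (cut + 1L):nrow(session$kin)
  sub <- function(idx, rows, shift) {
    t2 <- tr[rows, , drop = FALSE]
    t2$start_bin <- t2$start_bin - shift
    t2$target_onset_bin <- t2$target_onset_bin - shift
    t2$acquire_bin <- t2$acquire_bin - shift
    t2$end_bin <- t2$end_bin - shift
    kin <- session$kin[idx, , drop = FALSE]
    kin$bin <- seq_along(idx)
    rownames(kin) <- NULL
    sbp <- if (!is.null(session$sbp)) {
      sbp_matrix(unclass(session$sbp)[, idx, drop = FALSE],
                 bin_size = attr(session$sbp, "bin_size"),
                 channel_mask = attr(session$sbp, "channel_mask"))
    } else NULL
    ki <- if (!is.null(session$kin_intended)) {
      k <- session$kin_intended[idx, , drop = FALSE]
      k$bin <- seq_along(idx); rownames(k) <- NULL; k
    } else NULL
    session_bundle(sbp, kin, t2, mode = session$mode, meta = session$meta,
                   kin_intended = ki)
  }
  list(train = sub(idx1, seq_len(n_train), 0L),
       val = sub(idx2, (n_train + 1L):nrow(tr), cut))
}
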