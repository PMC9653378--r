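#' Two-finger random-target task configuration
#'
#' Geometry and timing of the random-target two-finger task. Positions are
#' expressed in normalized units `u` in `[0, 1]` per finger group
#' (0 = full extension, 1 = full flexion); velocities in u/s. Targets are
#' squares of width `target_width` (a fraction of the active range) centred
#' at random positions; both fingers must dwell inside their targets
#' continuously for the hold time to score a trial.
#'
#' @param target_width target size as a fraction of the active range of
#'   motion (default 0.15). The target radius used by the throughput formula
#'   is `target_width / 2`.
#' @param hold_time_train continuous hold required in training
#'   (manipulandum-control) mode, ms (default 750).
#' @param hold_time_test continuous hold required in testing (brain-control)
#'   mode, ms (default 500).
#' @param target_range fraction of the range used for target placement:
#'   1.0 for training, 0.95 for online decoding.
#' @param max_target_separation maximum allowed |target1 - target2|
#'   (default 0.5).
#' @param bin_size update interval, ms (50).
#' @param trial_timeout unsuccessful trials end after this many ms
#'   (default 10000).
#' @return an object of class `task_config`.
#' @export
#' @examples
#' task_config()
task_config <- function(target_width = 0.15,
                        hold_time_train = 750,
                        hold_time_test = 500,
                        target_range = 1.0,
                        max_target_separation = 0.5,
                        bin_size = 50,
                        trial_timeout = 10000) {
  stopifnot(target_width > 0, target_width < 1)
  if (hold_time_train <= 0 || hold_time_train %% bin_size != 0)
    stop("hold_time_train must be a positive multiple of bin_size")
  if (hold_time_test <= 0 || hold_time_test %% bin_size != 0)
    stop("hold_time_test must be a positive multiple of bin_size")
  stopifnot(target_range > 0, target_range <= 1,
            max_target_separation > 0, trial_timeout > 0)
  structure(list(
    n_fingers = 2L,
    target_width = target_width,
    hold_time_train = hold_time_train,
    hold_time_test = hold_time_test,
    target_range = target_range,
    max_target_separation = max_target_separation,
    bin_size = bin_size,
    trial_timeout = trial_timeout
  ), class = "task_config")
}

#' Simulated intention-driven user
#'
#' Parameters of the kinematic controller standing in for the animal: the
#' intended velocity is `clip(gain * (target - P), +/- v_max)`, passed
#' through a one-pole smoother with time constant `smooth_tau` and a
#' multiplicative log-normal speed jitter, and reacts to the displayed
#' (decoded) positions with a fixed delay. The delayed loop gain
#' `gain * (delay + smooth_tau)` is kept below pi/2 so the user settles on
#' target instead of oscillating, which gives bell-shaped speed profiles.
#'
#' @param gain proportional gain, 1/s (default 3).
#' @param v_max intended-speed ceiling, u/s (default 1.5).
#' @param smooth_tau one-pole smoothing time constant, ms (default 150).
#' @param reaction_delay delay before the user reacts to displayed positions
#'   and new targets, ms (default 150).
#' @param jitter_sd standard deviation of the log-normal multiplicative
#'   speed jitter (default 0.15; 0 disables jitter).
#' @param tremor_sd standard deviation (u/s) of additive per-finger,
#'   per-bin motor noise on the intended velocity (default 0; 0 disables
#'   it). This physiological tremor is part of the intention the cortex
#'   encodes, so it is decodable from the neural signal but unpredictable
#'   from the movement's own past.
#' @return an object of class `user_config`.
#' @export
user_config <- function(gain = 3, v_max = 1.5, smooth_tau = 150,
                        reaction_delay = 150, jitter_sd = 0.15,
                        tremor_sd = 0) {
  stopifnot(gain > 0, v_max > 0, smooth_tau >= 0,
            reaction_delay >= 0, jitter_sd >= 0, tremor_sd >= 0)
  structure(list(gain = gain, v_max = v_max, smooth_tau = smooth_tau,
                 reaction_delay = reaction_delay, jitter_sd = jitter_sd,
                 tremor_sd = tremor_sd),
            class = "user_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-finger random-target task\n")
  cat(sprintf("  target width: %.3f of range (radius %.3f)\n",
              x$target_width, x$target_width / 2))
  cat(sprintf("  hold: %d ms (train) / %d ms (test); timeout %d ms\n",
              x$hold_time_train, x$hold_time_test, x$trial_timeout))
  cat(sprintf("  target range: %.2f; max separation: %.2f; bin %d ms\n",
              x$target_range, x$max_target_separation, x$bin_size))
  invisible(x)
}
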