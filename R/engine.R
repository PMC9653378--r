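#' Generate a target pair
#'
#' Draws independent uniform target centres for the two fingers inside the
#' allowed placement range (`target_range` of the full range, centred), and
#' rejects draws until the pair satisfies the separation rule
#' (|t1 - t2| <= `max_target_separation`) and neither finger's target
#' interval (centre +/- width/2) intersects the corresponding interval of
#' the previous trial's targets.
#'
#' @param task a [task_config()].
#' @param prev previous trial's targets `c(t1, t2)` or `NULL`.
#' @param stream an RNG stream (internal) or `NULL` to use the global RNG.
#' @param cap maximum rejection draws before erroring (default 1000).
#' @return numeric `c(target1, target2)`.
#' @export
generate_targets <- function(task, prev = NULL, stream = NULL, cap = 1000) {
  lo <- (1 - task$target_range) / 2
  hi <- 1 - lo
  w2 <- task$target_width / 2
  draw <- function() runif(2, lo, hi)
  ok <- function(tg) {
    if (abs(tg[1] - tg[2]) > task$max_target_separation) return(FALSE)
    if (!is.null(prev)) {
      for (f in 1:2) {
        if (abs(tg[f] - prev[f]) < task$target_width) return(FALSE)
      }
    }
    TRUE
  }
  for (i in seq_len(cap)) {
    tg <- if (is.null(stream)) draw() else with_stream(stream, draw())
    if (ok(tg)) return(tg)
  }
  stop("generate_targets: resample cap exceeded; task geometry makes ",
       "non-overlapping targets infeasible")
}

# Core bin-by-bin simulation shared by the open-loop (manipulandum) user
# simulation and the closed-loop (brain-control) engine. The only difference
# between the two is which decoder closes the loop: the oracle decoder feeds
# the intended velocity straight back, which makes the closed loop
# bin-for-bin identical to an open-loop run of the same seed.
#
# Per 50-ms bin:
#   1. displayed positions integrate the previous bin's decoded velocity
#      (P_t = P_{t-1} + V_{t-1} * dt), then clip to [0, 1];
#   2. the user forms an intended velocity toward the current targets from
#      the *displayed* positions, both perceived with a reaction delay;
#   3. the encoder (with its neural lag) emits SBP from the intended
#      kinematics;
#   4. the decoder maps SBP to a velocity for the next integration step;
#   5. trial logic: continuous hold inside both targets for hold_bins wins;
#      trial_timeout ends the trial unsuccessfully.
simulate_loop <- function(decoder, enc, task, user, n_trials, seed,
                          mode = c("manipulandum", "brain_control"),
                          p0 = c(0.5, 0.5)) {
  mode <- match.arg(mode)
  stopifnot(n_trials >= 1)
  dt <- task$bin_size / 1000
  hold_ms <- if (mode == "manipulandum") task$hold_time_train else task$hold_time_test
  hold_bins <- as.integer(round(hold_ms / task$bin_size))
  timeout_bins <- as.integer(round(task$trial_timeout / task$bin_size))
  delay_bins <- as.integer(round(user$reaction_delay / task$bin_size))
  a_s <- if (user$smooth_tau > 0) exp(-task$bin_size / user$smooth_tau) else 0

  s_targets <- make_stream(seed, "targets")
  s_user <- make_stream(seed, "user")
  s_noise <- make_stream(seed, "encoder-noise")

  n_ch <- if (!is.null(enc)) enc$n_channels else 0L
  cap <- as.integer(n_trials * (timeout_bins + 1L) + 1L)
  P <- matrix(NA_real_, cap, 2)
  Vdec <- matrix(0, cap, 2)
  Vint <- matrix(0, cap, 2)
  Y <- if (n_ch > 0) matrix(0, n_ch, cap) else NULL
  tgt_hist <- matrix(NA_real_, cap, 2)

  dec_state <- if (!is.null(decoder)) decoder$init(n_ch, p0) else NULL

  trials <- vector("list", n_trials)
  trial <- 1L
  prev_tgt <- NULL
  tgt <- generate_targets(task, NULL, s_targets)
  onset <- 1L
  dwell <- 0L
  v_sm <- c(0, 0)
  t <- 0L

  while (trial <= n_trials) {
    t <- t + 1L
    if (t == 1L) {
      P[t, ] <- p0
    } else {
      P[t, ] <- pmin(pmax(P[t - 1L, ] + Vdec[t - 1L, ] * dt, 0), 1)
    }
    tgt_hist[t, ] <- tgt

    # --- user intention (delayed perception of display and targets) ---
    td <- max(t - delay_bins, 1L)
    v_cmd <- user$gain * (tgt_hist[td, ] - P[td, ])
    v_cmd <- pmin(pmax(v_cmd, -user$v_max), user$v_max)
    v_sm <- a_s * v_sm + (1 - a_s) * v_cmd
    v_now <- v_sm
    if (user$jitter_sd > 0) {
      j <- with_stream(s_user,
                       exp(rnorm(1, -user$jitter_sd^2 / 2, user$jitter_sd)))
      v_now <- v_now * j
    }
    if (user$tremor_sd > 0) {
      v_now <- v_now + with_stream(s_user, rnorm(2, 0, user$tremor_sd))
    }
    Vint[t, ] <- v_now

    # --- encoder ---
    if (n_ch > 0) {
      tl <- max(t - enc$lag_bins, 1L)
      kin_row <- cbind(P[tl, 1], P[tl, 2], Vint[tl, 1], Vint[tl, 2])
      mu <- encoder_expectation(enc, kin_row)
      if (enc$noise_scale > 0) {
        mu <- mu + with_stream(s_noise, rnorm(n_ch, 0, enc$noise_scale))
      }
      Y[, t] <- pmax(mu, 0)
    }

    # --- decoder ---
    if (is.null(decoder)) {
      Vdec[t, ] <- v_now
    } else {
      res <- decoder$step(dec_state, if (n_ch > 0) Y[, t] else NULL, v_now)
      Vdec[t, ] <- res$v
      dec_state <- res$state
    }

    # --- trial logic ---
    w2 <- task$target_width / 2
    in_tgt <- abs(P[t, 1] - tgt[1]) <= w2 && abs(P[t, 2] - tgt[2]) <= w2
    dwell <- if (in_tgt) dwell + 1L else 0L
    done <- FALSE
    if (dwell >= hold_bins) {
      trials[[trial]] <- list(trial = trial, target1 = tgt[1], target2 = tgt[2],
                              start_bin = onset, target_onset_bin = onset,
                              acquire_bin = t - hold_bins + 1L, end_bin = t,
                              success = TRUE,
                              d1 = abs(P[onset, 1] - tgt[1]),
                              d2 = abs(P[onset, 2] - tgt[2]))
      done <- TRUE
    } else if (t - onset + 1L >= timeout_bins) {
      trials[[trial]] <- list(trial = trial, target1 = tgt[1], target2 = tgt[2],
                              start_bin = onset, target_onset_bin = onset,
                              acquire_bin = NA_integer_, end_bin = t,
                              success = FALSE,
                              d1 = abs(P[onset, 1] - tgt[1]),
                              d2 = abs(P[onset, 2] - tgt[2]))
      done <- TRUE
    }
    if (done) {
      trial <- trial + 1L
      if (trial <= n_trials) {
        prev_tgt <- tgt
        tgt <- generate_targets(task, prev_tgt, s_targets)
        onset <- t + 1L
        dwell <- 0L
      }
    }
  }

  n <- t
  trials <- do.call(rbind, lapply(trials, as.data.frame))
  trials$excluded <- FALSE
  kin_dec <- data.frame(bin = seq_len(n), p1 = P[1:n, 1], p2 = P[1:n, 2],
                        v1 = Vdec[1:n, 1], v2 = Vdec[1:n, 2])
  kin_int <- data.frame(bin = seq_len(n), p1 = P[1:n, 1], p2 = P[1:n, 2],
                        v1 = Vint[1:n, 1], v2 = Vint[1:n, 2])
  sbp <- if (n_ch > 0) {
    sbp_matrix(Y[, 1:n, drop = FALSE], bin_size = task$bin_size,
               channel_mask = !enc$dead_channel_mask)
  } else NULL
  list(kin = kin_dec, kin_intended = kin_int, trials = trials, sbp = sbp)
}
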