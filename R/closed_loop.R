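#' Wrap a decoder for bin-by-bin closed-loop use
#'
#' Produces a handle with `init(n_channels, p0)` / `step(state, y, v_int)`
#' closures used by the closed-loop engine. Available kinds: a fitted
#' `kalman_decoder`, a trained `nn_decoder`, a `steady_state_kalman`, the
#' string `"oracle"` (returns the simulated user's intended velocity — the
#' perfect decoder), or the string `"zero"` (always zero velocity).
#'
#' @param x decoder object or kind string.
#' @param ... unused.
#' @return an object of class `decoder_handle`.
#' @export
as_decoder_handle <- function(x, ...) UseMethod("as_decoder_handle")

#' @export
as_decoder_handle.decoder_handle <- function(x, ...) x

#' @export
as_decoder_handle.character <- function(x, ...) {
  kind <- match.arg(x, c("oracle", "zero"))
  h <- if (kind == "oracle") {
    list(kind = "oracle",
         init = function(n_ch, p0) NULL,
         step = function(state, y, v_int) list(v = v_int, state = state))
  } else {
    list(kind = "zero",
         init = function(n_ch, p0) NULL,
         step = function(state, y, v_int) list(v = c(0, 0), state = state))
  }
  structure(h, class = "decoder_handle")
}

#' @export
as_decoder_handle.kalman_decoder <- function(x, ...) {
  params <- x
  structure(list(
    kind = "kalman", model = params,
    init = function(n_ch, p0) {
      if (n_ch != params$n_channels) stop("channel count mismatch")
      list(x = c(p0, 0, 0, 1), Sig = params$W, K = NULL, frozen = FALSE,
           ybuf = NULL)
    },
    step = function(state, y, v_int) {
      if (params$n_feature_lags == 3L) {
        if (is.null(state$ybuf)) state$ybuf <- cbind(y, y, y)
        state$ybuf <- cbind(y, state$ybuf[, 1:2, drop = FALSE])
        yy <- as.vector(state$ybuf)
      } else yy <- y
      if (!state$frozen) {
        st <- riccati_step(state$Sig, params$A, params$C, params$W, params$Q,
                           params$position_uncertainty)
        if (!is.null(state$K) && max(abs(st$K - state$K)) < 1e-13)
          state$frozen <- TRUE
        state$K <- st$K
        state$Sig <- st$Sig
      }
      xp <- params$A %*% state$x
      state$x <- xp + state$K %*% (yy - params$C %*% xp)
      list(v = as.numeric(state$x[3:4]), state = state)
    }), class = "decoder_handle")
}

#' @export
as_decoder_handle.steady_state_kalman <- function(x, ...) {
  ss <- x
  structure(list(
    kind = "steady_state_kalman", model = ss,
    init = function(n_ch, p0) {
      if (n_ch != ss$n_channels) stop("channel count mismatch")
      list(x = c(p0, 0, 0, 1), ybuf = NULL)
    },
    step = function(state, y, v_int) {
      if (ss$n_feature_lags == 3L) {
        if (is.null(state$ybuf)) state$ybuf <- cbind(y, y, y)
        state$ybuf <- cbind(y, state$ybuf[, 1:2, drop = FALSE])
        yy <- as.vector(state$ybuf)
      } else yy <- y
      state$x <- ss$M %*% state$x + ss$K_ss %*% yy
      state$x[5] <- 1
      list(v = as.numeric(state$x[3:4]), state = state)
    }), class = "decoder_handle")
}

#' @export
as_decoder_handle.nn_decoder <- function(x, ...) {
  model <- x
  cfg <- model$cfg
  structure(list(
    kind = "nn", model = model,
    init = function(n_ch, p0) {
      if (n_ch != cfg$n_electrodes) stop("channel count mismatch")
      list(buf = NULL)
    },
    step = function(state, y, v_int) {
      if (is.null(state$buf)) state$buf <- cbind(y, y, y)
      state$buf <- cbind(y, state$buf[, 1:2, drop = FALSE])
      inp <- if (cfg$use_time_layer) state$buf else matrix(y, 1)
      raw <- nn_forward(model, inp, 1L, training = FALSE)$out
      z <- raw * model$gain - model$median_offset
      v <- if (cfg$use_regularization) {
        z * model$target_sd + model$target_mean
      } else z
      list(v = as.numeric(v), state = state)
    }), class = "decoder_handle")
}

#' @export
print.decoder_handle <- function(x, ...) {
  cat(sprintf("Closed-loop decoder handle: %s\n", x$kind))
  invisible(x)
}

#' Run a closed-loop (brain-control) session
#'
#' Decoder-in-the-loop task execution: each 50-ms bin, the simulated user
#' forms an intended velocity toward the current targets from the displayed
#' (decoded) positions, the synthetic encoder emits SBP from the intended
#' kinematics, the decoder maps SBP to velocity, and the displayed
#' positions integrate the decoded velocity (clipped to the range edges;
#' velocity is not zeroed at the walls). Trials succeed after a continuous
#' `hold_time_test` inside both targets and fail at `trial_timeout`.
#'
#' @param decoder a decoder object or handle (see [as_decoder_handle()]).
#' @param enc the [make_encoder()] model generating SBP.
#' @param task a [task_config()]; use `target_range = 0.95` for the online
#'   protocol.
#' @param n_trials number of trials.
#' @param seed session seed.
#' @param user a [user_config()].
#' @return a `session_bundle` with `mode = "brain_control"`; `$kin` holds
#'   the decoded kinematics and `$kin_intended` the user's intention.
#' @export
run_closed_loop <- function(decoder, enc, task, n_trials, seed,
                            user = user_config()) {
  handle <- as_decoder_handle(decoder)
  res <- simulate_loop(handle, enc, task, user, n_trials, seed,
                       mode = "brain_control")
  session_bundle(res$sbp, res$kin, res$trials, mode = "brain_control",
                 meta = list(seed = seed, decoder = handle$kind),
                 kin_intended = res$kin_intended)
}

#' Alternating decoder comparison schedule
#'
#' Builds the A-B-A / B-A-B-A block plan used to compare two decoders
#' within a day, with a configurable number of leading trials per block
#' flagged as excluded from analysis (50 in the high-trial-count protocol,
#' 1 in the low-count protocol).
#'
#' @param decoders character vector of two decoder labels.
#' @param n_blocks number of blocks.
#' @param order `"AB"` or `"BA"` (reversed on alternate days).
#' @param trials_per_block trials in each block.
#' @param n_excluded leading trials of each block flagged excluded.
#' @return data frame `block, decoder, trials, n_excluded`.
#' @export
#' @examples
#' ab_alternation_schedule(c("RN", "RK"), 3, "AB")
ab_alternation_schedule <- function(decoders, n_blocks, order = c("AB", "BA"),
                                    trials_per_block = 100L,
                                    n_excluded = 50L) {
  order <- match.arg(order)
  if (length(decoders) != 2) stop("exactly 2 decoders are compared")
  seq2 <- if (order == "AB") decoders else rev(decoders)
  data.frame(block = seq_len(n_blocks),
             decoder = rep(seq2, length.out = n_blocks),
             trials = trials_per_block,
             n_excluded = n_excluded)
}
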