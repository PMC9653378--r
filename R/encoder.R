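#' Synthetic cortical population encoder
#'
#' Builds a per-channel tuning model mapping two-finger kinematics
#' `(P1, P2, V1, V2)` to nonnegative spike-band power (SBP). Each channel's
#' expected SBP blends an affine tuning with a sign-dependent saturating
#' velocity tuning:
#'
#' `baseline + w_p . (P1, P2) + (1 - mix) * w_v . (V1, V2)
#'  + mix * w_rect . sat(V1+, V1-, V2+, V2-)`
#'
#' evaluated on kinematics `lag_bins` bins in the past, plus additive
#' Gaussian noise, clipped at zero. The rectified components
#' (`V+ = max(V, 0)`, `V- = max(-V, 0)`) pass through a per-channel
#' saturating nonlinearity `sat(x) = s tanh(x / s)` (saturation level `s`
#' drawn per channel), emulating direction-tuned neurons whose firing
#' compresses at high speed — the regime where linear read-outs
#' under-predict fast movements. With `nonlinearity_mix = 0` the
#' expectation is exactly affine in the kinematic state; with
#' `nonlinearity_mix = 1` velocity tuning is fully rectified-saturating.
#' Weight draws are bounded and baselines large enough that the noiseless
#' expectation can never be clipped, so a linear regression can recover the
#' weights exactly in the linear limit. Dead channels emit noise only.
#'
#' @param n_channels number of recording channels (Utah arrays typically yield
#'   50-96 usable channels).
#' @param nonlinearity_mix scalar in `[0, 1]` scaling the rectified
#'   (sign-dependent) velocity component.
#' @param lag_bins nonnegative integer neural-to-kinematic lag in 50-ms bins
#'   (physiological lag; 0-3).
#' @param noise_scale standard deviation of the additive Gaussian noise on
#'   the pre-clip rate (arbitrary SBP units).
#' @param seed integer seed; the same seed reproduces the same encoder.
#' @param n_dead number of dead channels (noise only), default 0.
#' @return an object of class `encoder_model`.
#' @export
#' @examples
#' enc <- make_encoder(64, nonlinearity_mix = 0.5, lag_bins = 1,
#'                     noise_scale = 0.3, seed = 1)
#' enc
make_encoder <- function(n_channels, nonlinearity_mix = 0.5, lag_bins = 1L,
                         noise_scale = 0.3, seed = 1L, n_dead = 0L) {
  if (length(n_channels) != 1 || n_channels < 1)
    stop("n_channels must be a positive count")
  stopifnot(nonlinearity_mix >= 0, nonlinearity_mix <= 1,
            lag_bins >= 0, noise_scale >= 0, n_dead >= 0,
            n_dead < n_channels)
  n_channels <- as.integer(n_channels)
  s <- make_stream(seed, "encoder-params")
  with_stream(s, {
    baseline <- runif(n_channels, 4, 6)
    # columns: P1, P2, V1, V2
    lin <- cbind(runif(n_channels, -0.25, 0.25),
                 runif(n_channels, -0.25, 0.25),
                 runif(n_channels, -0.5, 0.5),
                 runif(n_channels, -0.5, 0.5))
    # Sign-dependent tuning dominated by unsigned speed: each channel gets a
    # magnitude m (random sign: excited or suppressed by movement) and a
    # moderate directional asymmetry d, so w+ = m(1+d), w- = m(1-d).
    # Unsigned speed components are invisible to linear read-outs, which is
    # the regime where the nonlinear decoder has something to gain - as in
    # motor cortex, where much of the population modulates with speed.
    m1 <- sample(c(-1, 1), n_channels, TRUE) * runif(n_channels, 0.2, 0.6)
    m2 <- sample(c(-1, 1), n_channels, TRUE) * runif(n_channels, 0.2, 0.6)
    d1 <- runif(n_channels, -0.4, 0.4)
    d2 <- runif(n_channels, -0.4, 0.4)
    # columns: V1+, V1-, V2+, V2-
    rect <- cbind(m1 * (1 + d1), m1 * (1 - d1), m2 * (1 + d2), m2 * (1 - d2))
    sat_level <- runif(n_channels, 0.3, 0.9)
    dead <- if (n_dead > 0) sample(n_channels, n_dead) else integer(0)
  })
  # Guarantee preferred directions span both fingers and both signs.
  if (n_channels >= 4) {
    lin[1, 3] <- abs(lin[1, 3]); lin[2, 3] <- -abs(lin[2, 3])
    lin[3, 4] <- abs(lin[3, 4]); lin[4, 4] <- -abs(lin[4, 4])
  }
  mask <- rep(TRUE, n_channels)
  mask[dead] <- FALSE
  colnames(lin) <- c("P1", "P2", "V1", "V2")
  colnames(rect) <- c("V1p", "V1n", "V2p", "V2n")
  structure(list(
    n_channels = n_channels,
    baseline = baseline,
    linear_weights = lin,
    rect_weights = rect,
    sat_level = sat_level,
    nonlinearity_mix = nonlinearity_mix,
    lag_bins = as.integer(lag_bins),
    noise_scale = noise_scale,
    dead_channel_mask = !mask,
    seed = seed
  ), class = "encoder_model")
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf(
    "Synthetic SBP encoder: %d channels (%d dead), mix %.2f, lag %d bins, noise %.2f\n",
    x$n_channels, sum(x$dead_channel_mask), x$nonlinearity_mix,
    x$lag_bins, x$noise_scale))
  invisible(x)
}

# Expected (noiseless, pre-clip) SBP for a kinematic matrix [P1 P2 V1 V2].
encoder_expectation <- function(enc, kin_mat) {
  mix <- enc$nonlinearity_mix
  lin <- enc$linear_weights
  lin[, 3:4] <- (1 - mix) * lin[, 3:4]
  mu <- enc$baseline + lin %*% t(kin_mat)
  if (mix > 0) {
    rectf <- rbind(pmax(kin_mat[, 3], 0), pmax(-kin_mat[, 3], 0),
                   pmax(kin_mat[, 4], 0), pmax(-kin_mat[, 4], 0))
    # per-channel saturating response s * tanh(x / s)
    for (j in 1:4) {
      sat <- enc$sat_level * tanh(outer(1 / enc$sat_level, rectf[j, ]))
      mu <- mu + mix * enc$rect_weights[, j] * sat
    }
  }
  mu[enc$dead_channel_mask, ] <- 0
  mu  # channels x bins
}

#' Encode kinematics into spike-band power
#'
#' Applies the encoder's tuning model to a kinematics table, with the
#' encoder's neural-to-kinematic lag: the SBP at bin `t` derives from the
#' kinematics at bin `t - lag_bins` (the earliest bin is replicated for the
#' first `lag_bins` bins). Additive Gaussian noise (sd `noise_scale`) is
#' drawn from the session's encoder-noise stream and the result clipped at
#' zero.
#'
#' @param kin a kinematics data frame with columns `p1, p2, v1, v2`
#'   (see [simulate_user_kinematics()]).
#' @param enc an [make_encoder()] model.
#' @param seed integer seed for the noise stream.
#' @return an `sbp_matrix`: channels x bins matrix with attributes
#'   `bin_size` (ms) and `channel_mask`.
#' @export
encode_sbp <- function(kin, enc, seed = 1L) {
  stopifnot(inherits(enc, "encoder_model"))
  n <- nrow(kin)
  if (n <= enc$lag_bins)
    stop("kinematics must be longer than the encoder lag")
  idx <- pmax(seq_len(n) - enc$lag_bins, 1L)
  kin_mat <- cbind(kin$p1, kin$p2, kin$v1, kin$v2)[idx, , drop = FALSE]
  mu <- encoder_expectation(enc, kin_mat)
  if (enc$noise_scale > 0) {
    s <- make_stream(seed, "encoder-noise")
    noise <- with_stream(s, matrix(rnorm(length(mu), 0, enc$noise_scale),
                                   nrow(mu), ncol(mu)))
    mu <- mu + noise
  }
  sbp_matrix(pmax(mu, 0), bin_size = 50,
             channel_mask = !enc$dead_channel_mask)
}

#' Construct an SBP matrix
#'
#' @param values channels x bins matrix of nonnegative spike-band power.
#' @param bin_size bin width in ms.
#' @param channel_mask logical vector of included channels.
#' @return an `sbp_matrix`.
#' @export
sbp_matrix <- function(values, bin_size = 50, channel_mask = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("SBP values must be nonnegative")
  if (is.null(channel_mask)) channel_mask <- rep(TRUE, nrow(values))
  if (length(channel_mask) != nrow(values))
    stop("channel_mask length must equal the channel count")
  structure(values, bin_size = bin_size, channel_mask = channel_mask,
            class = c("sbp_matrix", "matrix", "array"))
}

#' @export
print.sbp_matrix <- function(x, ...) {
  cat(sprintf("SBP matrix: %d channels x %d bins (%d ms bins, %d masked-in)\n",
              nrow(x), ncol(x), attr(x, "bin_size"),
              sum(attr(x, "channel_mask"))))
  invisible(x)
}
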