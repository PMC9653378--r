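#' Estimate the optimal neural-to-kinematic lag
#'
#' Physiological lag between cortical activity and movement is found by
#' maximizing, over candidate lags `0..max_lag`, the mean absolute Pearson
#' correlation between each finger's velocity at bin `t - lag` and each
#' channel's SBP at bin `t`. Ties go to the smallest lag.
#'
#' @param session a `session_bundle` with SBP.
#' @param max_lag largest lag (in 50-ms bins) to consider.
#' @return integer lag in bins.
#' @export
estimate_optimal_lag <- function(session, max_lag = 3) {
  stopifnot(max_lag >= 0)
  y <- unclass(session$sbp)
  n <- ncol(y)
  if (n <= max_lag + 2) stop("session shorter than max_lag")
  v <- cbind(session$kin$v1, session$kin$v2)
  score <- vapply(0:max_lag, function(lag) {
    vv <- v[seq_len(n - lag), , drop = FALSE]
    yy <- y[, (1 + lag):n, drop = FALSE]
    keep <- apply(yy, 1, stats::sd) > 0
    mean(abs(stats::cor(t(yy[keep, , drop = FALSE]), vv)))
  }, numeric(1))
  as.integer(which.max(score) - 1L)
}

# State design matrix [P1 P2 V1 V2 1] from a kinematics data frame.
state_matrix <- function(kin) {
  cbind(kin$p1, kin$p2, kin$v1, kin$v2, 1)
}

#' Fit a position-velocity Kalman filter
#'
#' Fits the two-finger position-velocity Kalman filter on a training
#' session. The 5-dimensional kinematic state is `(P1, P2, V1, V2, 1)`.
#' The observation map `C` (channels x 5) is estimated by least squares of
#' the SBP at bin `t` on the state at bin `t - lag_bins`. The transition
#' matrix `A` has its position rows fixed to the physical integration
#' relationship (`P_t = P_{t-1} + dt V_{t-1}`, dt = 0.05 s) and its 2x2
#' velocity block (including cross-terms) estimated by least squares of
#' `V_t` on `V_{t-1}`. `W` is the velocity-block process-noise covariance
#' and `Q` the full measurement-noise covariance, both from regression
#' residuals. With `n_feature_lags = 3` the observation stacks bins
#' `t, t-1, t-2` into one augmented feature vector (a time-lagged-feature
#' Kalman filter).
#'
#' The returned decoder follows the ReFIT convention of a Kalman gain
#' without position uncertainty: the position (and offset) rows/columns of
#' the a-priori covariance are zeroed each predict step, so innovations are
#' routed to the velocities only and decoded position exactly integrates
#' decoded velocity. Set `position_uncertainty = TRUE` for the classic
#' filter.
#'
#' @param session a `session_bundle` with SBP and kinematics.
#' @param lag_bins neural-to-kinematic lag in bins (default 1, one 50-ms
#'   bin).
#' @param n_feature_lags 1 (plain) or 3 (time-lagged features).
#' @param drop_position drop the position columns from the observation
#'   regression (they are then fixed at zero in `C`; the default). With
#'   position columns included and a gain computed without position
#'   uncertainty, the position-innovation feedback can render the decode
#'   recursion unstable, so positions are not regressed on SBP unless
#'   explicitly requested.
#' @param position_uncertainty keep position uncertainty in the gain
#'   (classic Kalman filter) instead of the ReFIT convention.
#' @return an object of class `kalman_decoder`.
#' @export
#' @examples
#' enc <- make_encoder(16, 0, 0, 0, seed = 1)
#' ses <- generate_session(task_config(), enc, 20, seed = 2)
#' kf <- fit_kalman(ses, lag_bins = 0)
#' kf
fit_kalman <- function(session, lag_bins = 1L, n_feature_lags = 1L,
                       drop_position = TRUE, position_uncertainty = FALSE) {
  if (!n_feature_lags %in% c(1L, 3L))
    stop("n_feature_lags must be 1 or 3")
  kin <- session$kin
  n <- nrow(kin)
  if (n < 100) stop("session must have at least 100 bins")
  y <- unclass(session$sbp)
  fit_kalman_core(y, kin, lag_bins, n_feature_lags, drop_position,
                  position_uncertainty,
                  channel_mask = attr(session$sbp, "channel_mask"))
}

fit_kalman_core <- function(y, kin, lag_bins, n_feature_lags, drop_position,
                            position_uncertainty, channel_mask = NULL,
                            obs_rows = NULL, vel_rows = NULL) {
  dt <- 0.05
  lag_bins <- as.integer(lag_bins)
  n <- nrow(kin)
  n_ch <- nrow(y)
  X_all <- state_matrix(kin)

  # --- observation model ---
  if (n_feature_lags == 3L) {
    ystack <- rbind(y,
                    y[, c(1L, seq_len(n - 1L)), drop = FALSE],
                    y[, c(1L, 1L, seq_len(n - 2L)), drop = FALSE])
  } else {
    ystack <- y
  }
  t_obs <- (lag_bins + 1L):n
  if (!is.null(obs_rows)) t_obs <- intersect(t_obs, obs_rows)
  X <- X_all[t_obs - lag_bins, , drop = FALSE]
  Yt <- t(ystack[, t_obs, drop = FALSE])
  cols <- if (drop_position) c(3L, 4L, 5L) else 1:5
  Xc <- X[, cols, drop = FALSE]
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) {
    nm <- c("P1", "P2", "V1", "V2", "offset")[cols]
    bad <- nm[setdiff(seq_len(ncol(Xc)), qx$pivot[seq_len(qx$rank)])]
    stop("singular fit: rank-deficient regressors (", paste(bad, collapse = ", "), ")")
  }
  B <- qr.coef(qx, Yt)                     # |cols| x (n_feature_lags*channels)
  C <- matrix(0, nrow(ystack), 5)
  C[, cols] <- t(B)
  resid <- Yt - Xc %*% B
  Q <- crossprod(resid) / nrow(resid)

  # --- transition model (velocity block) ---
  V <- cbind(kin$v1, kin$v2)
  pairs_to <- 2:n
  if (!is.null(vel_rows)) pairs_to <- intersect(pairs_to, vel_rows)
  Vt <- V[pairs_to, , drop = FALSE]
  Vp <- V[pairs_to - 1L, , drop = FALSE]
  Av <- t(qr.coef(qr(Vp), Vt))             # 2x2, no intercept: the transition has no velocity offset
  Wv <- crossprod(Vt - Vp %*% t(Av)) / nrow(Vt)
  A <- diag(5)
  A[1, 3] <- dt
  A[2, 4] <- dt
  A[3:4, 3:4] <- Av
  W <- matrix(0, 5, 5)
  W[3:4, 3:4] <- Wv

  structure(list(
    A = A, C = C, W = W, Q = Q,
    lag_bins = lag_bins, n_feature_lags = as.integer(n_feature_lags),
    dt = dt, n_channels = n_ch,
    position_uncertainty = position_uncertainty,
    drop_position = drop_position,
    channel_mask = if (is.null(channel_mask)) rep(TRUE, n_ch) else channel_mask,
    n_train_bins = length(t_obs)
  ), class = "kalman_decoder")
}

#' @export
print.kalman_decoder <- function(x, ...) {
  cat(sprintf(
    "Position-velocity Kalman filter: %d channels, lag %d bins, %d feature lag(s)\n",
    x$n_channels, x$lag_bins, x$n_feature_lags))
  cat(sprintf("  gain convention: %s; velocity block A_vv =\n",
              if (x$position_uncertainty) "classic (position uncertainty)"
              else "ReFIT (no position uncertainty)"))
  print(round(x$A[3:4, 3:4], 4))
  invisible(x)
}

#' @export
coef.kalman_decoder <- function(object, ...) object$C

# Moore-Penrose solve, for innovation covariances that are singular in the
# noiseless limit (Q -> 0 with a low-rank a-priori covariance).
psd_solve <- function(S, B) {
  out <- tryCatch(solve(S, B), error = function(e) NULL)
  if (!is.null(out)) {
    rc <- rcond(S)
    if (is.finite(rc) && rc > 1e-12) return(out)
  }
  sv <- svd(S)
  tol <- max(dim(S)) * max(sv$d) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  sv$v %*% (dinv * (t(sv$u) %*% B))
}

# One Riccati predict/update step under the decoder's gain convention.
riccati_step <- function(Sig, A, C, W, Q, position_uncertainty) {
  Sp <- A %*% Sig %*% t(A) + W
  if (!position_uncertainty) {
    Sp[c(1, 2, 5), ] <- 0
    Sp[, c(1, 2, 5)] <- 0
  }
  S <- C %*% Sp %*% t(C) + Q
  K <- t(psd_solve(S, C %*% Sp))
  list(K = K, Sig = Sp - K %*% C %*% Sp)
}

#' Run the recursive Kalman decode
#'
#' Standard predict/update recursion (`x_pred = A x`, then
#' `x = x_pred + K_t (y_t - C x_pred)`). The gain recursion is iterated
#' until it converges, then frozen. Because SBP at bin `t` encodes
#' kinematics at `t - lag_bins`, the output row `t` is the filter's estimate
#' of the kinematic state `lag_bins` bins in the past: the decode carries
#' the physiological lag as a display delay.
#'
#' @param params a `kalman_decoder`.
#' @param sbp an `sbp_matrix` (channels x bins).
#' @param p0 initial positions (default `c(0.5, 0.5)`).
#' @return kinematics data frame with attribute `gain_path` (sup-norm
#'   change of `K_t` per bin) and `K_ss` (the converged gain).
#' @export
decode_kalman <- function(params, sbp, p0 = c(0.5, 0.5)) {
  y <- unclass(sbp)
  if (nrow(y) != params$n_channels)
    stop("channel count does not match the fitted observation map")
  n <- ncol(y)
  if (params$n_feature_lags == 3L) {
    y <- rbind(y,
               y[, c(1L, seq_len(n - 1L)), drop = FALSE],
               y[, c(1L, 1L, seq_len(n - 2L)), drop = FALSE])
  }
  A <- params$A; C <- params$C; W <- params$W; Q <- params$Q
  x <- c(p0, 0, 0, 1)
  Sig <- W
  K <- NULL
  frozen <- FALSE
  gain_path <- numeric(n)
  out <- matrix(0, n, 4)
  for (t in seq_len(n)) {
    if (!frozen) {
      st <- riccati_step(Sig, A, C, W, Q, params$position_uncertainty)
      dK <- if (is.null(K)) Inf else max(abs(st$K - K))
      gain_path[t] <- dK
      K <- st$K
      Sig <- st$Sig
      if (dK < 1e-13) frozen <- TRUE
    } else gain_path[t] <- 0
    xp <- A %*% x
    x <- xp + K %*% (y[, t] - C %*% xp)
    out[t, ] <- x[1:4]
  }
  kin <- data.frame(bin = seq_len(n), p1 = out[, 1], p2 = out[, 2],
                    v1 = out[, 3], v2 = out[, 4])
  attr(kin, "gain_path") <- gain_path
  attr(kin, "K_ss") <- K
  kin
}

#' @export
predict.kalman_decoder <- function(object, sbp, p0 = c(0.5, 0.5), ...) {
  decode_kalman(object, sbp, p0)
}

#' @export
summary.kalman_decoder <- function(object, ...) {
  print(object)
  cat(sprintf("  trained on %d bins; W velocity block:\n", object$n_train_bins))
  print(signif(object$W[3:4, 3:4], 3))
  invisible(object)
}

#' Fit a Kalman filter on a restricted velocity range
#'
#' Trains a classic Kalman filter (position uncertainty kept, learnable
#' velocity block, physiological lag) using only bins whose velocities are
#' mostly positive (`side = "positive"`: both fingers' velocities greater
#' than -sigma/2) or mostly negative (`side = "negative"`: both less than
#' +sigma/2), with sigma the per-finger standard deviation of true velocity
#' over the whole session. Used to show that range-restricted linear fits
#' reach higher speeds than a full-range fit.
#'
#' @param session a `session_bundle`.
#' @param side `"positive"` or `"negative"`.
#' @param lag_bins physiological lag; `NULL` estimates it from the session.
#' @return a `kalman_decoder` with attribute `side` and `retained_fraction`.
#' @export
fit_restricted_kalman <- function(session, side = c("positive", "negative"),
                                  lag_bins = NULL) {
  side <- match.arg(side)
  kin <- session$kin
  sig <- c(stats::sd(kin$v1), stats::sd(kin$v2))
  qual <- if (side == "positive") {
    kin$v1 > -sig[1] / 2 & kin$v2 > -sig[2] / 2
  } else {
    kin$v1 < sig[1] / 2 & kin$v2 < sig[2] / 2
  }
  rows <- which(qual)
  if (length(rows) < 100)
    stop(sprintf("too few qualifying bins for KF%s: %d (need >= 100)",
                 if (side == "positive") "+" else "-", length(rows)))
  if (is.null(lag_bins)) lag_bins <- estimate_optimal_lag(session, 3)
  # A bin enters the observation regression when its *state* sample (at
  # t - lag) qualifies; velocity pairs need both ends qualifying.
  obs_rows <- rows + lag_bins
  n <- nrow(kin)
  vel_rows <- (2:n)[qual[1:(n - 1L)] & qual[2:n]]
  fit <- fit_kalman_core(unclass(session$sbp), kin, lag_bins, 1L,
                         drop_position = FALSE, position_uncertainty = TRUE,
                         channel_mask = attr(session$sbp, "channel_mask"),
                         obs_rows = obs_rows, vel_rows = vel_rows)
  attr(fit, "side") <- side
  attr(fit, "sigma") <- sig
  attr(fit, "retained_fraction") <- mean(qual)
  fit
}

#' Ridge-regression velocity readout (linear baseline)
#'
#' Closed-form ridge regression from the SBP at bin `t` (no time history)
#' to the two finger velocities at bin `t`, with unpenalized intercept.
#'
#' @param session a `session_bundle`.
#' @param lambda ridge constant (the reference value is `1e-4`).
#' @return object of class `ridge_decoder` with a `predict` method.
#' @export
fit_ridge <- function(session, lambda = 1e-4) {
  stopifnot(lambda >= 0)
  X <- t(unclass(session$sbp))
  Y <- cbind(session$kin$v1, session$kin$v2)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  B <- solve(crossprod(Xc) + lambda * diag(ncol(X)), crossprod(Xc, Yc))
  structure(list(B = B, intercept = ym - drop(xm %*% B), lambda = lambda,
                 n_channels = ncol(X)),
            class = "ridge_decoder")
}

#' @export
predict.ridge_decoder <- function(object, sbp, ...) {
  X <- t(unclass(sbp))
  V <- sweep(X %*% object$B, 2, object$intercept, `+`)
  data.frame(bin = seq_len(nrow(V)), v1 = V[, 1], v2 = V[, 2])
}

#' @export
print.ridge_decoder <- function(x, ...) {
  cat(sprintf("Ridge velocity readout: %d channels, lambda = %g\n",
              x$n_channels, x$lambda))
  invisible(x)
}
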