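#' Steady-state form of a fitted Kalman filter
#'
#' Iterates the gain recursion of a fitted Kalman filter to its fixed point
#' `K_ss` and rewrites the decode as a weighted sum of the previous estimate
#' and the current neural estimate. Writing `M = (I - K_ss C) A`, the
#' velocity update is
#'
#' `V_t = G V_{t-1} + F P_{t-1} + c + K_v y_t`
#'
#' with `G` the velocity block of `M`, `K_v` the velocity rows of `K_ss`,
#' and `F`, `c` the (small) position/offset coupling terms from the
#' innovation. The scalar smoothing factor is summarized as
#' `alpha = mean(diag(G))` and the gain/readout split as
#' `K_v = (1 - alpha) * beta * D` with `D` normalized to unit mean column
#' norm — so the update reads `V_t ~ alpha V_{t-1} + (1 - alpha) beta D y_t`.
#' The stored object keeps the exact operators, so its decode reproduces the
#' recursive Kalman decode to machine precision once the recursive gain has
#' converged.
#'
#' The smoothing factor and gain apply to the velocity kinematics only;
#' positions always integrate velocity.
#'
#' @param params a `kalman_decoder`.
#' @param tol fixed-point tolerance on the gain (sup norm).
#' @param max_iter maximum gain iterations.
#' @return an object of class `steady_state_kalman` with fields `alpha`,
#'   `beta`, `D`, and the exact update operators.
#' @export
steady_state_form <- function(params, tol = 1e-12, max_iter = 5000) {
  Sig <- params$W
  K <- NULL
  for (i in seq_len(max_iter)) {
    st <- riccati_step(Sig, params$A, params$C, params$W, params$Q,
                       params$position_uncertainty)
    if (!is.null(K) && max(abs(st$K - K)) < tol) {
      K <- st$K
      break
    }
    K <- st$K
    Sig <- st$Sig
    if (i == max_iter) stop("Kalman gain did not converge to steady state")
  }
  M <- (diag(5) - K %*% params$C) %*% params$A
  G <- M[3:4, 3:4]
  K_v <- K[3:4, , drop = FALSE]
  alpha <- mean(diag(G))
  if (alpha >= 1) stop("extracted smoothing factor alpha >= 1")
  Draw <- K_v / (1 - alpha)
  beta <- mean(sqrt(colSums(Draw^2)))
  D <- Draw / beta
  structure(list(alpha = alpha, beta = beta, D = D,
                 G = G, F_pos = M[3:4, 1:2], c_off = M[3:4, 5],
                 K_v = K_v, K_ss = K, M = M,
                 A = params$A, C = params$C, dt = params$dt,
                 n_channels = params$n_channels,
                 n_feature_lags = params$n_feature_lags,
                 lag_bins = params$lag_bins),
            class = "steady_state_kalman")
}

#' @export
print.steady_state_kalman <- function(x, ...) {
  cat(sprintf(
    "Steady-state Kalman form: alpha = %.4f, beta = %.4g (%d channels)\n",
    x$alpha, x$beta, x$n_channels))
  invisible(x)
}

#' One literal steady-state update
#'
#' The scalar-form update `x_t = alpha x_{t-1} + (1 - alpha) beta D y_t`,
#' exposed on its own for reasoning about fixed points and gain/smoothing
#' tuning.
#'
#' @param x_prev previous estimate (length-2F vector or scalar).
#' @param y observation vector.
#' @param alpha smoothing factor in `[0, 1)`.
#' @param beta gain factor (> 0).
#' @param D readout matrix (2F x channels) or scalar.
#' @return updated estimate.
#' @export
#' @examples
#' steady_state_update(0, 1, alpha = 0.5, beta = 2, D = 1)  # -> 1; fix pt 2
steady_state_update <- function(x_prev, y, alpha, beta, D) {
  drop(alpha * x_prev + (1 - alpha) * beta * (D %*% y))
}

#' Decode with the steady-state form
#'
#' Runs the exact fixed-gain recursion of a [steady_state_form()] object:
#' positions integrate decoded velocity (`P_t = P_{t-1} + dt V_{t-1}` under
#' the ReFIT gain convention) and velocities follow the smoothed
#' gain-weighted update. Matches [decode_kalman()] bin-for-bin once the
#' recursive gain has converged.
#'
#' @param ss a `steady_state_kalman`.
#' @param sbp an `sbp_matrix`.
#' @param p0 initial positions.
#' @return kinematics data frame.
#' @export
decode_steady_state <- function(ss, sbp, p0 = c(0.5, 0.5)) {
  y <- unclass(sbp)
  if (nrow(y) != ss$n_channels) stop("channel count mismatch")
  n <- ncol(y)
  if (ss$n_feature_lags == 3L) {
    y <- rbind(y,
               y[, c(1L, seq_len(n - 1L)), drop = FALSE],
               y[, c(1L, 1L, seq_len(n - 2L)), drop = FALSE])
  }
  x <- c(p0, 0, 0, 1)
  out <- matrix(0, n, 4)
  for (t in seq_len(n)) {
    x <- ss$M %*% x + ss$K_ss %*% y[, t]
    x[5] <- 1
    out[t, ] <- x[1:4]
  }
  data.frame(bin = seq_len(n), p1 = out[, 1], p2 = out[, 2],
             v1 = out[, 3], v2 = out[, 4])
}

#' @export
predict.steady_state_kalman <- function(object, sbp, p0 = c(0.5, 0.5), ...) {
  decode_steady_state(object, sbp, p0)
}

#' Tune the gain and smoothing of a steady-state Kalman decoder
#'
#' Online hyper-parameter tuning: the smoothing factor is scaled to
#' `alpha' = min(alpha * alpha_scale, 1 - 1e-6)` and the gain to
#' `beta' = beta * beta_scale`. The history operator is rescaled by
#' `alpha'/alpha` and the neural-input side (gain rows, innovation coupling
#' and offset) by `beta_scale * (1 - alpha') / (1 - alpha)`, which reduces
#' exactly to `x_t = alpha' x_{t-1} + (1 - alpha') beta' D y_t` in the
#' scalar case. The reference tuning scales alpha by 1.25 and beta by 1.2.
#'
#' @param ss a `steady_state_kalman`.
#' @param alpha_scale multiplicative factor on the smoothing term.
#' @param beta_scale multiplicative factor on the gain term.
#' @return a retuned `steady_state_kalman`.
#' @export
tune_gain_smoothing <- function(ss, alpha_scale = 1.25, beta_scale = 1.2) {
  eps <- 1e-6
  a_new <- ss$alpha * alpha_scale
  if (a_new >= 1) {
    warning(sprintf("scaled alpha = %.4f clipped to %g", a_new, 1 - eps))
    a_new <- 1 - eps
  }
  hist_scale <- a_new / ss$alpha
  in_scale <- beta_scale * (1 - a_new) / (1 - ss$alpha)
  out <- ss
  out$alpha <- a_new
  out$beta <- ss$beta * beta_scale
  out$G <- ss$G * hist_scale
  out$K_v <- ss$K_v * in_scale
  out$F_pos <- ss$F_pos * in_scale
  out$c_off <- ss$c_off * in_scale
  out$M[3:4, 3:4] <- out$G
  out$M[3:4, 1:2] <- out$F_pos
  out$M[3:4, 5] <- out$c_off
  out$K_ss[3:4, ] <- out$K_v
  out
}
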