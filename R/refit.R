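#' Re-orient decoded velocities toward the known targets
#'
#' The intention-retraining step of ReFIT. For each bin inside a trial, let
#' `d_f = target_f - P_f` be the signed distance of finger `f` to its
#' target centre.
#'
#' * `method = "rotate"`: the velocity vector is replaced by
#'   `||(V1, V2)|| * (d1, d2) / ||(d1, d2)||` — proportional to each
#'   finger's distance to target, keeping the total velocity magnitude
#'   constant. On target (`d = (0, 0)`) the result is `(0, 0)`.
#' * `method = "flip"`: per finger, `V_f` is sign-flipped iff
#'   `sign(V_f) != sign(d_f)` and both are nonzero.
#'
#' Positions are never modified. Bins outside any trial are excluded from
#' the returned kinematics and reported via the `included_bins` attribute.
#'
#' @param kin decoded kinematics data frame (`bin, p1, p2, v1, v2`).
#' @param trials trial-record data frame with targets and bin ranges.
#' @param method `"rotate"` or `"flip"`.
#' @return kinematics data frame restricted to in-trial bins, with
#'   attribute `included_bins` (original bin indices retained).
#' @export
refit_intention_kinematics <- function(kin, trials,
                                       method = c("rotate", "flip")) {
  method <- match.arg(method)
  if (is.null(trials) || nrow(trials) == 0)
    stop("trial list is empty: intention retraining needs targets")
  n <- nrow(kin)
  tgt <- matrix(NA_real_, n, 2)
  for (i in seq_len(nrow(trials))) {
    idx <- trials$start_bin[i]:trials$end_bin[i]
    tgt[idx, 1] <- trials$target1[i]
    tgt[idx, 2] <- trials$target2[i]
  }
  keep <- which(!is.na(tgt[, 1]))
  if (length(keep) < n)
    message(sprintf("refit: excluded %d bins outside any trial", n - length(keep)))
  out <- kin[keep, , drop = FALSE]
  d1 <- tgt[keep, 1] - out$p1
  d2 <- tgt[keep, 2] - out$p2
  if (method == "rotate") {
    vmag <- sqrt(out$v1^2 + out$v2^2)
    dmag <- sqrt(d1^2 + d2^2)
    scale <- ifelse(dmag > 0, vmag / dmag, 0)
    out$v1 <- scale * d1
    out$v2 <- scale * d2
  } else {
    flip1 <- sign(out$v1) != sign(d1) & out$v1 != 0 & d1 != 0
    flip2 <- sign(out$v2) != sign(d2) & out$v2 != 0 & d2 != 0
    out$v1 <- ifelse(flip1, -out$v1, out$v1)
    out$v2 <- ifelse(flip2, -out$v2, out$v2)
  }
  rownames(out) <- NULL
  attr(out, "included_bins") <- keep
  out
}

#' ReFIT retraining of the Kalman filter
#'
#' Applies [refit_intention_kinematics()] to the decoded kinematics of a
#' closed-loop (brain-control) run and refits the Kalman filter on the
#' re-oriented velocities, as in the second training pass of the ReFIT
#' Kalman filter.
#'
#' @param session a brain-control `session_bundle` (decoded kinematics in
#'   `$kin`).
#' @param method intention-correction rule, `"rotate"` (default) or
#'   `"flip"`.
#' @param lag_bins,n_feature_lags passed to [fit_kalman()].
#' @return a `kalman_decoder`.
#' @export
refit_kalman <- function(session, method = c("rotate", "flip"),
                         lag_bins = 1L, n_feature_lags = 1L) {
  method <- match.arg(method)
  if (session$mode != "brain_control")
    stop("refit_kalman needs a closed-loop (brain_control) session")
  kin2 <- refit_intention_kinematics(session$kin, session$trials, method)
  keep <- attr(kin2, "included_bins")
  sbp2 <- sbp_matrix(unclass(session$sbp)[, keep, drop = FALSE],
                     bin_size = attr(session$sbp, "bin_size"),
                     channel_mask = attr(session$sbp, "channel_mask"))
  kin2$bin <- seq_len(nrow(kin2))
  ses2 <- session_bundle(sbp2, kin2, local({
    tr <- session$trials
    tr$start_bin <- pmin(pmax(match(tr$start_bin, keep), 1L), nrow(kin2))
    tr$target_onset_bin <- tr$start_bin
    tr$end_bin <- pmin(pmax(match(tr$end_bin, keep), 1L), nrow(kin2))
    tr$acquire_bin <- NA_integer_
    tr
  }), mode = "brain_control", meta = session$meta)
  fit_kalman(ses2, lag_bins = lag_bins, n_feature_lags = n_feature_lags)
}
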