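#' ReFIT retraining of the neural network
#'
#' Builds a truth signal from the decoder's own closed-loop output by
#' flipping each finger's velocity whenever it pointed away from that
#' finger's target (`sign(V_f) != sign(target_f - P_f)`, zeros never
#' flipped), then continues Adam optimization from the existing weights for
#' a further `tc$iterations` (500 by default). Batch-norm running
#' statistics keep updating during retraining. The output gain is either
#' recomputed on the retraining run (default) or the previous gain is
#' scaled by 0.75.
#'
#' @param model the trained `nn_decoder` used in the closed-loop run.
#' @param run the brain-control `session_bundle` produced with `model`.
#' @param tc a [train_config()]; defaults to 500 iterations without
#'   redistribution.
#' @param gain_mode `"recompute"` or `"scale"` (x 0.75).
#' @param val optional fresh validation `session_bundle` for the gain
#'   recomputation. By default the retraining run itself (with its flipped
#'   truth signal) is used, but a closed-loop run from a poorly calibrated
#'   decoder has a biased velocity distribution that distorts the median
#'   offset, so supplying open-loop validation data is more robust.
#' @return the retrained `nn_decoder`.
#' @export
refit_nn <- function(model, run,
                     tc = train_config(iterations = 500L,
                                       redistribute = FALSE),
                     gain_mode = c("recompute", "scale"),
                     val = NULL) {
  gain_mode <- match.arg(gain_mode)
  if (run$mode != "brain_control")
    stop("refit_nn needs a closed-loop (brain_control) session with targets")
  cfg <- model$cfg
  y <- unclass(run$sbp)
  if (nrow(y) != cfg$n_electrodes) stop("channel count mismatch")
  kin <- run$kin
  truth <- nn_flip_targets(kin, run$trials)
  keep <- attr(truth, "included_bins")
  Vt <- cbind(truth$v1, truth$v2)
  targets <- if (cfg$use_regularization) {
    sweep(sweep(Vt, 2, model$target_mean), 2, model$target_sd, `/`)
  } else Vt
  pool <- if (tc$redistribute) {
    redistribute_velocity_samples(truth, tc$n_redistributed, tc$seed)
  } else seq_along(keep)
  s <- make_stream(tc$seed, "nn-refit")
  st <- adam_init(model$params)
  B <- tc$batch_rows
  for (it in seq_len(tc$iterations)) {
    j <- with_stream(s, sample(pool, B, replace = TRUE))
    idx <- keep[j]
    inp <- nn_input(y, idx, cfg)
    fw <- with_stream(s, nn_forward(model, inp, B, training = TRUE))
    model$running <- fw$running
    err <- fw$out - targets[j, , drop = FALSE]
    loss <- mean(err * err)
    if (!is.finite(loss))
      stop("retraining diverged (non-finite loss) at iteration ", it)
    Gr <- nn_backward(model, fw, 2 * err / length(err), B)
    upd <- adam_step(model$params, Gr, st, tc)
    model$params <- upd$P
    st <- upd$st
  }
  if (gain_mode == "scale") {
    model$gain <- model$gain * 0.75
  } else {
    if (is.null(val))
      val <- session_bundle(run$sbp, truth_session_kin(truth, keep, run),
                            run$trials, mode = "brain_control")
    model <- nn_calibrate_gain(model, val)
  }
  model$trained <- TRUE
  model
}

# Flip rule: per finger, negate the decoded velocity when it points away
# from the target; zero velocities and on-target bins are left unchanged.
nn_flip_targets <- function(kin, trials) {
  if (is.null(trials) || nrow(trials) == 0)
    stop("trial list is empty: ReFIT needs targets")
  n <- nrow(kin)
  tgt <- matrix(NA_real_, n, 2)
  for (i in seq_len(nrow(trials))) {
    idx <- trials$start_bin[i]:trials$end_bin[i]
    tgt[idx, 1] <- trials$target1[i]
    tgt[idx, 2] <- trials$target2[i]
  }
  keep <- which(!is.na(tgt[, 1]))
  out <- kin[keep, , drop = FALSE]
  d1 <- tgt[keep, 1] - out$p1
  d2 <- tgt[keep, 2] - out$p2
  f1 <- sign(out$v1) != sign(d1) & out$v1 != 0 & d1 != 0
  f2 <- sign(out$v2) != sign(d2) & out$v2 != 0 & d2 != 0
  out$v1 <- ifelse(f1, -out$v1, out$v1)
  out$v2 <- ifelse(f2, -out$v2, out$v2)
  rownames(out) <- NULL
  attr(out, "included_bins") <- keep
  out
}

truth_session_kin <- function(truth, keep, run) {
  k <- run$kin
  k$v1[keep] <- truth$v1
  k$v2[keep] <- truth$v2
  k
}

#' Nodal contributions of the final hidden layer
#'
#' Each node of the final hidden layer is rectified (nonnegative), so the
#' product of its activation `N_k` and its output weight `W_L[k, f]`
#' contributes either only positive or only negative velocity to finger
#' `f`: nodes are classed positive or negative by the sign of `W_L[k, f]`.
#' Contributions are computed on the deterministic prediction path and
#' summarized in three true-velocity regimes per finger (positive:
#' `v > sigma`; negative: `v < -sigma`; near zero: `|v| < sigma / 4`, with
#' sigma that finger's true-velocity standard deviation).
#'
#' @param model a trained `nn_decoder` with at least 2 FC layers.
#' @param sbp an `sbp_matrix`.
#' @param kin matching true kinematics (for the velocity regimes).
#' @return an object of class `nodal_report`: `node_sign` (nodes x 2),
#'   `contribution` (list per finger of bins x nodes matrices),
#'   `regime_means` (group x regime x finger array plus `$pooled` averaged
#'   over fingers), and the raw output/bias for the decomposition check.
#' @export
nodal_contributions <- function(model, sbp, kin) {
  cfg <- model$cfg
  if (cfg$n_fc_layers < 2) stop("nodal analysis needs at least 2 FC layers")
  y <- unclass(sbp)
  L <- cfg$n_fc_layers
  fw <- nn_forward(model, nn_input(y, seq_len(ncol(y)), cfg), ncol(y),
                   training = FALSE)
  N <- fw$cache$fc_in[[L]]                       # bins x nodes, rectified
  W <- model$params[[paste0("W", L)]]            # nodes x 2
  bias <- model$params[[paste0("b", L)]]
  vtrue <- cbind(kin$v1, kin$v2)
  sig <- apply(vtrue, 2, stats::sd)
  contribution <- list()
  rm_arr <- array(NA_real_, c(2, 3, 2),
                  dimnames = list(c("positive_nodes", "negative_nodes"),
                                  c("positive_v", "negative_v", "near_zero"),
                                  c("finger1", "finger2")))
  for (f in 1:2) {
    Cf <- sweep(N, 2, W[, f], `*`)               # bins x nodes
    contribution[[f]] <- Cf
    pos_nodes <- W[, f] > 0
    regimes <- list(positive_v = vtrue[, f] > sig[f],
                    negative_v = vtrue[, f] < -sig[f],
                    near_zero = abs(vtrue[, f]) < sig[f] / 4)
    for (r in seq_along(regimes)) {
      rows <- which(regimes[[r]])
      if (length(rows) > 0) {
        rm_arr[1, r, f] <- mean(Cf[rows, pos_nodes, drop = FALSE])
        rm_arr[2, r, f] <- mean(Cf[rows, !pos_nodes, drop = FALSE])
      }
    }
  }
  structure(list(node_sign = sign(W),
                 contribution = contribution,
                 regime_means = rm_arr,
                 pooled = apply(rm_arr, c(1, 2), mean, na.rm = TRUE),
                 raw_output = fw$out, bias = bias, sigma = sig),
            class = "nodal_report")
}

#' @export
print.nodal_report <- function(x, ...) {
  cat("Nodal-contribution report (pooled over fingers)\n")
  print(signif(x$pooled, 3))
  invisible(x)
}
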