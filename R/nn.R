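#' Shallow feed-forward network configuration
#'
#' Architecture of the velocity-decoding network: an optional time-feature
#' layer — a learned linear map, shared across electrodes, from the 3 most
#' recent 50-ms bins to `n_time_features` features per electrode, followed
#' by batch normalization over the feature channels and a rectifier, then
#' flattened to `n_time_features * n_electrodes` — feeding `n_fc_layers`
#' fully connected layers. Hidden layers are ordered linear -> dropout ->
#' batch norm -> ReLU; the final layer is linear with 2 outputs (one
#' velocity per finger group). Without the time layer the input is the
#' current 50-ms bin only (no time history).
#'
#' @param n_electrodes number of input electrodes.
#' @param n_time_bins history bins consumed by the time layer (3).
#' @param n_time_features learned time features per electrode (16).
#' @param n_fc_layers number of fully connected layers (2 or 4).
#' @param hidden hidden width (256).
#' @param use_time_layer include the time-feature layer.
#' @param use_regularization include dropout + batch normalization (and
#'   z-scored training targets).
#' @param dropout_rate dropout probability (0.5).
#' @param relu_identity test hook: replace rectifiers by the identity
#'   (used to check the degenerate linear limit); also permits
#'   `n_fc_layers = 1`.
#' @return an `nn_config` list.
#' @export
nn_config <- function(n_electrodes, n_time_bins = 3L, n_time_features = 16L,
                      n_fc_layers = 4L, hidden = 256L,
                      use_time_layer = TRUE, use_regularization = TRUE,
                      dropout_rate = 0.5, relu_identity = FALSE) {
  stopifnot(n_electrodes >= 1, n_time_bins == 3L, n_time_features >= 1,
            hidden >= 1, dropout_rate >= 0, dropout_rate < 1)
  if (n_fc_layers < 2 && !relu_identity)
    stop("n_fc_layers must be at least 2")
  structure(list(n_electrodes = as.integer(n_electrodes),
                 n_time_bins = 3L,
                 n_time_features = as.integer(n_time_features),
                 n_fc_layers = as.integer(n_fc_layers),
                 hidden = as.integer(hidden),
                 use_time_layer = use_time_layer,
                 use_regularization = use_regularization,
                 dropout_rate = dropout_rate,
                 relu_identity = relu_identity),
            class = "nn_config")
}

#' Training recipe for the network
#'
#' @param iterations Adam iterations (3500 for the main network, 500 for
#'   ReFIT retraining).
#' @param batch_rows mini-batch size: 64 random time steps, each carrying
#'   its 3-bin history.
#' @param learning_rate Adam step size (1e-4 online; 2e-5 for offline
#'   ablations at full iteration counts).
#' @param weight_decay coupled L2 penalty added to every gradient (1e-2).
#' @param beta1,beta2 Adam moment decays (0.9, 0.999).
#' @param redistribute impose a triangular velocity distribution on the
#'   training samples (see [redistribute_velocity_samples()]).
#' @param n_redistributed number of redistributed training samples (20000).
#' @param seed seed for initialization, batch sampling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(iterations = 3500L, batch_rows = 64L,
                         learning_rate = 1e-4, weight_decay = 1e-2,
                         beta1 = 0.9, beta2 = 0.999,
                         redistribute = TRUE, n_redistributed = 20000L,
                         seed = 1L) {
  stopifnot(iterations >= 1, batch_rows >= 1, learning_rate > 0,
            weight_decay >= 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            n_redistributed >= 0)
  structure(list(iterations = as.integer(iterations),
                 batch_rows = as.integer(batch_rows),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, redistribute = redistribute,
                 n_redistributed = as.integer(n_redistributed),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an (untrained) velocity-decoding network
#'
#' Kaiming (He) initialization for every weight matrix
#' (`sd = sqrt(2 / fan_in)`), zero biases, unit batch-norm scales, zero
#' shifts; running statistics start at mean 0 / variance 1.
#'
#' @param cfg an [nn_config()].
#' @param seed integer seed (reproducible initialization).
#' @return an object of class `nn_decoder` (untrained).
#' @export
#' @examples
#' net <- build_network(nn_config(96), seed = 1)
#' n_parameters(net)  # 527202, which rounds to 5e5
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "nn_config"))
  E <- cfg$n_electrodes
  Fk <- cfg$n_time_features
  L <- cfg$n_fc_layers
  in_dim <- if (cfg$use_time_layer) Fk * E else E
  widths <- c(rep(cfg$hidden, L - 1L), 2L)
  ins <- c(in_dim, widths[-L])
  P <- list()
  R <- list()
  s <- make_stream(seed, "nn-init")
  with_stream(s, {
    if (cfg$use_time_layer) {
      P$Wt <- matrix(rnorm(3 * Fk, 0, sqrt(2 / 3)), 3, Fk)
      P$bt <- numeric(Fk)
      if (cfg$use_regularization) {
        P$gt <- rep(1, Fk); P$ht <- numeric(Fk)
        R$rmt <- numeric(Fk); R$rvt <- rep(1, Fk)
      }
    }
    for (i in seq_len(L)) {
      P[[paste0("W", i)]] <- matrix(rnorm(ins[i] * widths[i], 0,
                                          sqrt(2 / ins[i])),
                                    ins[i], widths[i])
      P[[paste0("b", i)]] <- numeric(widths[i])
      if (cfg$use_regularization && i < L) {
        P[[paste0("g", i)]] <- rep(1, widths[i])
        P[[paste0("h", i)]] <- numeric(widths[i])
        R[[paste0("rm", i)]] <- numeric(widths[i])
        R[[paste0("rv", i)]] <- rep(1, widths[i])
      }
    }
  })
  structure(list(cfg = cfg, params = P, running = R,
                 target_mean = c(0, 0), target_sd = c(1, 1),
                 gain = 1, median_offset = c(0, 0),
                 trained = FALSE, seed = seed, val_correlation = NA_real_),
            class = "nn_decoder")
}

#' Number of learnable parameters
#'
#' Counts every learned weight, bias and batch-norm scale/shift (running
#' statistics are not learned and are excluded).
#'
#' @param model an `nn_decoder`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Flattened width of the time-feature layer
#'
#' @param cfg an [nn_config()].
#' @return `n_time_features * n_electrodes` (0 when the time layer is off).
#' @export
time_layer_width <- function(cfg) {
  if (!cfg$use_time_layer) return(0L)
  cfg$n_time_features * cfg$n_electrodes
}

#' @export
print.nn_decoder <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("Shallow feed-forward velocity decoder (%s)\n",
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  %d electrodes; %s%d FC layer(s) x %d hidden; %s\n",
              cfg$n_electrodes,
              if (cfg$use_time_layer)
                sprintf("time layer (%d features -> width %d) + ",
                        cfg$n_time_features, time_layer_width(cfg)) else "",
              cfg$n_fc_layers, cfg$hidden,
              if (cfg$use_regularization) "dropout + batch norm" else "no regularization"))
  cat(sprintf("  %d learnable parameters; gain %.3f\n", n_parameters(x), x$gain))
  if (is.finite(x$val_correlation))
    cat(sprintf("  validation correlation %.3f\n", x$val_correlation))
  invisible(x)
}

#' @export
coef.nn_decoder <- function(object, ...) object$params

# ---- internal forward/backward -------------------------------------------

bn_eps <- 1e-5
bn_momentum <- 0.1

bn_forward <- function(Z, g, h, rm, rv, training) {
  if (training) {
    bt <- bn_train_forward(Z, g, h, bn_eps)
    m <- nrow(Z)
    vunb <- if (m > 1) bt$va * m / (m - 1) else bt$va
    new_rm <- (1 - bn_momentum) * rm + bn_momentum * bt$mu
    new_rv <- (1 - bn_momentum) * rv + bn_momentum * vunb
    list(out = bt$out, xhat = bt$xhat, ivar = bt$ivar,
         rm = new_rm, rv = new_rv)
  } else {
    ivar <- 1 / sqrt(rv + bn_eps)
    xhat <- col_affine(Z, rm, ivar, numeric(length(rm)))
    out <- col_affine(xhat, numeric(length(g)), g, h)
    list(out = out, xhat = xhat, ivar = ivar, rm = rm, rv = rv)
  }
}

bn_backward <- function(dout, xhat, ivar, g, training) {
  dg <- colSums(dout * xhat)
  dh <- colSums(dout)
  dxhat <- col_mul(dout, g)
  if (!training) {
    return(list(dx = col_mul(dxhat, ivar), dg = dg, dh = dh))
  }
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  list(dx = bn_backward_dx(dxhat, xhat, s1, s2, ivar), dg = dg, dh = dh)
}

# Build the network input for time steps `tb` from an SBP matrix
# (channels x bins). History indices are clamped at the first bin, so the
# earliest bin is replicated for the first two time steps of a session.
nn_input <- function(y, tb, cfg) {
  if (cfg$use_time_layer) {
    i0 <- tb
    i1 <- pmax(tb - 1L, 1L)
    i2 <- pmax(tb - 2L, 1L)
    cbind(as.vector(t(y[, i0, drop = FALSE])),
          as.vector(t(y[, i1, drop = FALSE])),
          as.vector(t(y[, i2, drop = FALSE])))
  } else {
    t(y[, tb, drop = FALSE])
  }
}

relu <- function(x, identity = FALSE) if (identity) x else x * (x > 0)

# Forward pass. `inp` is the matrix from nn_input(); B is the number of
# time steps in the batch. Returns the raw 2-column output plus a cache for
# backprop and updated running statistics.
nn_forward <- function(model, inp, B, training = FALSE) {
  cfg <- model$cfg
  P <- model$params
  R <- model$running
  reg <- cfg$use_regularization
  cache <- list()
  if (cfg$use_time_layer) {
    Zt <- col_add(inp %*% P$Wt, P$bt)             # (B*E) x F
    cache$Tin <- inp
    if (reg) {
      bn <- bn_forward(Zt, P$gt, P$ht, R$rmt, R$rvt, training)
      R$rmt <- bn$rm; R$rvt <- bn$rv
      cache$bn_t <- bn
      Zt2 <- bn$out
    } else Zt2 <- Zt
    cache$pre_relu_t <- Zt2
    At <- relu(Zt2, cfg$relu_identity)
    # flatten (B*E) x F -> B x (E*F): rows are (e-major, b fastest), so a
    # plain dim change gives feature blocks in electrode-major order; the
    # following dense layer is order-agnostic as long as both passes agree
    X <- At
    dim(X) <- c(B, cfg$n_electrodes * cfg$n_time_features)
  } else {
    X <- inp
  }
  cache$fc_in <- list()
  cache$drop_mask <- list()
  cache$bn_fc <- list()
  cache$pre_relu <- list()
  L <- cfg$n_fc_layers
  for (i in seq_len(L)) {
    cache$fc_in[[i]] <- X
    Z <- col_add(X %*% P[[paste0("W", i)]], P[[paste0("b", i)]])
    if (i == L) { X <- Z; break }
    if (reg) {
      if (training && cfg$dropout_rate > 0) {
        keep <- 1 - cfg$dropout_rate
        mask <- matrix(runif(length(Z)) < keep, nrow(Z), ncol(Z)) / keep
        Z <- Z * mask
        cache$drop_mask[[i]] <- mask
      }
      bn <- bn_forward(Z, P[[paste0("g", i)]], P[[paste0("h", i)]],
                       R[[paste0("rm", i)]], R[[paste0("rv", i)]], training)
      R[[paste0("rm", i)]] <- bn$rm; R[[paste0("rv", i)]] <- bn$rv
      cache$bn_fc[[i]] <- bn
      Z <- bn$out
    }
    cache$pre_relu[[i]] <- Z
    X <- relu(Z, cfg$relu_identity)
  }
  list(out = X, cache = cache, running = R)
}

# Backward pass for the mean-squared-error objective; returns gradients
# named like the parameters.
nn_backward <- function(model, fw, dout, B, training = TRUE) {
  cfg <- model$cfg
  P <- model$params
  reg <- cfg$use_regularization
  cache <- fw$cache
  G <- list()
  L <- cfg$n_fc_layers
  dX <- dout
  for (i in rev(seq_len(L))) {
    if (i < L) {
      pre <- cache$pre_relu[[i]]
      if (!cfg$relu_identity) dX <- dX * (pre > 0)
      if (reg) {
        bn <- cache$bn_fc[[i]]
        bb <- bn_backward(dX, bn$xhat, bn$ivar, P[[paste0("g", i)]], training)
        G[[paste0("g", i)]] <- bb$dg
        G[[paste0("h", i)]] <- bb$dh
        dX <- bb$dx
        if (training && cfg$dropout_rate > 0)
          dX <- dX * cache$drop_mask[[i]]
      }
    }
    Xin <- cache$fc_in[[i]]
    G[[paste0("W", i)]] <- crossprod(Xin, dX)
    G[[paste0("b", i)]] <- colSums(dX)
    dX <- tcrossprod(dX, P[[paste0("W", i)]])
  }
  if (cfg$use_time_layer) {
    E <- cfg$n_electrodes; Fk <- cfg$n_time_features
    dAt <- dX
    dim(dAt) <- c(B * E, Fk)
    pre <- cache$pre_relu_t
    if (!cfg$relu_identity) dAt <- dAt * (pre > 0)
    if (reg) {
      bn <- cache$bn_t
      bb <- bn_backward(dAt, bn$xhat, bn$ivar, P$gt, training)
      G$gt <- bb$dg
      G$ht <- bb$dh
      dAt <- bb$dx
    }
    G$Wt <- crossprod(cache$Tin, dAt)
    G$bt <- colSums(dAt)
  }
  G
}

adam_init <- function(P) {
  list(m = lapply(P, function(p) p * 0),
       v = lapply(P, function(p) p * 0), t = 0L)
}

adam_step <- function(P, G, st, tc) {
  st$t <- st$t + 1L
  b1 <- tc$beta1; b2 <- tc$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(P)) {
    upd <- adam_update(P[[nm]], G[[nm]], st$m[[nm]], st$v[[nm]],
                       tc$learning_rate, tc$weight_decay, b1, b2, c1, c2,
                       1e-8)
    P[[nm]] <- upd$p
    st$m[[nm]] <- upd$m
    st$v[[nm]] <- upd$v
  }
  list(P = P, st = st)
}

# Raw (unscaled) network output for the given time steps, prediction mode.
nn_raw_output <- function(model, y, tb = seq_len(ncol(y))) {
  inp <- nn_input(y, tb, model$cfg)
  nn_forward(model, inp, length(tb), training = FALSE)$out
}

#' Train the velocity-decoding network
#'
#' Mean-squared-error training with Adam on 64 x 3 mini-batches (64 random
#' time steps, each with 150 ms of history). Training targets are z-scored
#' per finger (when regularization is on), and a triangular velocity
#' redistribution can re-weight the training pool. After training, the
#' unlearned output gain and median offset are computed on the validation
#' set ([compute_gain_factor()]), so the prediction path returns
#' physical-unit velocities.
#'
#' @param train training `session_bundle` (manipulandum-control).
#' @param val validation `session_bundle`.
#' @param cfg an [nn_config()]; defaults to the 4-layer + time-layer
#'   network sized to the session's channel count.
#' @param tc a [train_config()].
#' @return a trained `nn_decoder`.
#' @export
train_nn <- function(train, val, cfg = NULL, tc = train_config()) {
  y <- unclass(train$sbp)
  if (is.null(cfg)) cfg <- nn_config(n_electrodes = nrow(y))
  if (nrow(y) != cfg$n_electrodes)
    stop("training session channel count does not match cfg$n_electrodes")
  if (nrow(unclass(val$sbp)) != cfg$n_electrodes)
    stop("validation session channel count does not match cfg$n_electrodes")
  model <- build_network(cfg, tc$seed)
  V <- cbind(train$kin$v1, train$kin$v2)
  if (cfg$use_regularization) {
    model$target_mean <- colMeans(V)
    model$target_sd <- apply(V, 2, stats::sd)
    targets <- sweep(sweep(V, 2, model$target_mean), 2, model$target_sd, `/`)
  } else {
    targets <- V
  }
  pool <- if (tc$redistribute) {
    redistribute_velocity_samples(train$kin, tc$n_redistributed, tc$seed)
  } else seq_len(nrow(V))
  s <- make_stream(tc$seed, "nn-train")
  st <- adam_init(model$params)
  B <- tc$batch_rows
  for (it in seq_len(tc$iterations)) {
    idx <- with_stream(s, sample(pool, B, replace = TRUE))
    inp <- nn_input(y, idx, cfg)
    fw <- with_stream(s, nn_forward(model, inp, B, training = TRUE))
    model$running <- fw$running
    err <- fw$out - targets[idx, , drop = FALSE]
    loss <- mean(err * err)
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at iteration ", it)
    dout <- 2 * err / length(err)
    Gr <- nn_backward(model, fw, dout, B)
    upd <- adam_step(model$params, Gr, st, tc)
    model$params <- upd$P
    st <- upd$st
  }
  model$trained <- TRUE
  model <- nn_calibrate_gain(model, val)
  pred <- predict_nn(model, val$sbp)
  model$val_correlation <- mean(c(stats::cor(pred$v1, val$kin$v1),
                                  stats::cor(pred$v2, val$kin$v2)))
  model
}

# Gain/median calibration on a validation session: peaks are matched on the
# same scale the network is trained on (z-scored when regularization is on).
nn_calibrate_gain <- function(model, val) {
  raw <- nn_raw_output(model, unclass(val$sbp))
  V <- cbind(val$kin$v1, val$kin$v2)
  actual <- if (model$cfg$use_regularization) {
    sweep(sweep(V, 2, model$target_mean), 2, model$target_sd, `/`)
  } else V
  gf <- compute_gain_factor(actual, raw)
  model$gain <- gf$gain
  model$median_offset <- gf$median_offset
  model
}

#' Predict finger velocities with a trained network
#'
#' Deterministic prediction path: dropout off, batch normalization uses its
#' running statistics. The raw output is multiplied by the unlearned gain,
#' the median offset subtracted, and the result mapped back to physical
#' units (u/s) through the stored target scaling.
#'
#' @param model a trained `nn_decoder`.
#' @param sbp an `sbp_matrix` (channels x bins). The first two bins of a
#'   session replicate the earliest bin as history.
#' @return data frame `bin, v1, v2` in u/s.
#' @export
predict_nn <- function(model, sbp) {
  y <- unclass(sbp)
  if (nrow(y) != model$cfg$n_electrodes)
    stop("channel count does not match the trained network")
  raw <- nn_raw_output(model, y)
  z <- sweep(raw * model$gain, 2, model$median_offset)
  V <- if (model$cfg$use_regularization) {
    sweep(sweep(z, 2, model$target_sd, `*`), 2, model$target_mean, `+`)
  } else z
  data.frame(bin = seq_len(ncol(y)), v1 = V[, 1], v2 = V[, 2])
}

#' @export
predict.nn_decoder <- function(object, sbp, ...) predict_nn(object, sbp)

# Local maxima of |v| above one standard deviation of the series, separated
# by at least `min_sep` bins.
find_speed_peaks <- function(v, min_sep = 5L) {
  a <- abs(v)
  thr <- stats::sd(v)
  n <- length(a)
  if (n < 3) return(integer(0))
  cand <- which(a[2:(n - 1)] >= a[1:(n - 2)] & a[2:(n - 1)] > a[3:n] &
                  a[2:(n - 1)] > thr) + 1L
  if (length(cand) == 0) return(integer(0))
  keep <- integer(0)
  last <- -Inf
  for (i in cand[order(-a[cand])]) {
    if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Unlearned output gain and median offset
#'
#' The gain equals the average magnitude of the actual-velocity peaks
#' divided by the average magnitude of the predicted-velocity peaks, where
#' peaks are local maxima of |v| exceeding one standard deviation of the
#' series, at least 250 ms apart, pooled over fingers. The median offset is
#' the per-finger median of the gain-scaled predictions (subtracted to
#' approximate a zero-mean signal).
#'
#' @param actual_v actual velocities (vector or 2-column matrix).
#' @param predicted_v predicted velocities, same shape.
#' @return list with `gain` (scalar) and `median_offset` (per finger).
#' @export
compute_gain_factor <- function(actual_v, predicted_v) {
  A <- as.matrix(actual_v); Pm <- as.matrix(predicted_v)
  stopifnot(nrow(A) == nrow(Pm), ncol(A) == ncol(Pm))
  apk <- unlist(lapply(seq_len(ncol(A)), function(f) {
    i <- find_speed_peaks(A[, f]); abs(A[i, f])
  }))
  ppk <- unlist(lapply(seq_len(ncol(Pm)), function(f) {
    i <- find_speed_peaks(Pm[, f]); abs(Pm[i, f])
  }))
  if (length(apk) == 0 || length(ppk) == 0)
    stop("no velocity peaks found; consider lowering the peak threshold")
  gain <- mean(apk) / mean(ppk)
  list(gain = gain, median_offset = apply(Pm * gain, 2, stats::median))
}

#' Resample bins toward a triangular velocity distribution
#'
#' Importance resampling of time bins so that the pooled sampled velocities
#' of both fingers approximate a symmetric triangular density on
#' `[-4 sigma, 4 sigma]` peaked at zero, with sigma the standard deviation
#' of the pooled velocities. Each bin is weighted by the product of the two
#' fingers' density ratios (triangular target over a per-finger kernel
#' density estimate), which makes the pooled resampled density converge to
#' the target when the fingers are close to independent.
#'
#' @param kin kinematics data frame with `v1, v2`.
#' @param n number of indices to draw (with replacement); 0 gives an empty
#'   index vector.
#' @param seed integer seed.
#' @param pool_fingers pool both fingers into one target distribution
#'   (default TRUE); otherwise weights use finger 1 only.
#' @param sigma scale of the triangular target (its support is
#'   `[-4 sigma, 4 sigma]`); defaults to the standard deviation of the
#'   pooled velocities.
#' @return integer vector of `n` bin indices.
#' @export
redistribute_velocity_samples <- function(kin, n, seed = 1L,
                                          pool_fingers = TRUE,
                                          sigma = NULL) {
  v1 <- kin$v1; v2 <- kin$v2
  sig <- if (is.null(sigma)) stats::sd(c(v1, v2)) else sigma
  if (!is.finite(sig) || sig == 0)
    stop("degenerate input: velocities have zero variance")
  if (n == 0) return(integer(0))
  tri <- function(v) pmax(0, (1 - abs(v) / (4 * sig)) / (4 * sig))
  # per-finger density by equal-width histogram: unbiased per bin, so the
  # importance ratios do not inherit kernel smoothing bias at the peak
  dens_ratio <- function(v) {
    nb <- max(20L, min(60L, length(v) %/% 200L))
    br <- seq(min(v) - 1e-12, max(v) + 1e-12, length.out = nb + 1)
    h <- hist(v, breaks = br, plot = FALSE)
    g <- h$density[pmin(pmax(findInterval(v, br), 1L), nb)]
    g <- pmax(g, 0.01 / (8 * sig))
    tri(v) / g
  }
  w <- if (pool_fingers) dens_ratio(v1) * dens_ratio(v2) else dens_ratio(v1)
  if (sum(w) <= 0) stop("degenerate input: no mass inside [-4 sigma, 4 sigma]")
  s <- make_stream(seed, "redistribute")
  with_stream(s, sample(length(w), n, replace = TRUE, prob = w))
}
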