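test_that("the reference architecture has the documented size", {
  cfg <- nn_config(96)
  net <- build_network(cfg, seed = 1)
  # independent per-layer hand count: time layer 3*16+16 and BN 2*16;
  # FC1 1536*256+256, BN 512; FC2/FC3 256*256+256, BN 512; FC4 256*2+2
  by_hand <- as.integer((3 * 16 + 16) + 32 +
                          (1536 * 256 + 256) + 512 +
                          (256 * 256 + 256) + 512 +
                          (256 * 256 + 256) + 512 +
                          (256 * 2 + 2))
  expect_identical(n_parameters(net), by_hand)
  expect_identical(by_hand, 527202L)
  expect_equal(signif(n_parameters(net), 1), 5e5)
  expect_identical(time_layer_width(cfg), 1536L)
})

test_that("initialization and prediction are deterministic", {
  cfg <- nn_config(8, hidden = 16)
  n1 <- build_network(cfg, seed = 3)
  n2 <- build_network(cfg, seed = 3)
  expect_identical(n1$params, n2$params)
  y <- sbp_matrix(matrix(abs(rnorm(8 * 30)), 8, 30))
  p1 <- predict_nn(n1, y)
  p2 <- predict_nn(n1, y)
  expect_identical(p1, p2)
})

test_that("the network is feed-forward: duplicate bins give duplicate outputs", {
  net <- build_network(nn_config(6, hidden = 8, use_time_layer = FALSE),
                       seed = 4)
  col <- abs(rnorm(6))
  y <- sbp_matrix(matrix(col, 6, 5))
  p <- predict_nn(net, y)
  expect_true(all(abs(diff(p$v1)) == 0) && all(abs(diff(p$v2)) == 0))
})

test_that("training is seeded end-to-end", {
  enc <- make_encoder(8, 0.3, 0, 0.2, seed = 5)
  ses <- generate_session(task_config(), enc, 25, seed = 6)
  sp <- split_session(ses, 20)
  cfg <- nn_config(8, n_fc_layers = 2, hidden = 16, n_time_features = 4)
  tc <- train_config(iterations = 60, learning_rate = 1e-3, seed = 7,
                     redistribute = FALSE)
  m1 <- train_nn(sp$train, sp$val, cfg, tc)
  m2 <- train_nn(sp$train, sp$val, cfg, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$gain, m2$gain)
})

test_that("the network recovers a noiseless linear mapping", {
  enc <- make_encoder(16, 0, 0, 0, seed = 8)
  ses <- generate_session(task_config(), enc, 150, seed = 9)
  sp <- split_session(ses, 120)
  cfg <- nn_config(16, n_fc_layers = 2, hidden = 64)
  nn <- train_nn(sp$train, sp$val, cfg,
                 train_config(iterations = 500, learning_rate = 1e-3,
                              weight_decay = 2e-3, redistribute = FALSE,
                              seed = 10))
  pred <- predict_nn(nn, sp$val$sbp)
  r <- velocity_correlation(pred, sp$val$kin)
  expect_gt(min(r$per_finger), 0.95)
})

test_that("predictions track a lagged encoder within one bin", {
  enc <- make_encoder(12, 0.3, 1, 0.1, seed = 11)
  ses <- generate_session(task_config(), enc, 120, seed = 12)
  sp <- split_session(ses, 100)
  nn <- train_nn(sp$train, sp$val,
                 nn_config(12, n_fc_layers = 2, hidden = 32),
                 train_config(iterations = 400, learning_rate = 1e-3,
                              weight_decay = 2e-3, redistribute = FALSE,
                              seed = 13))
  pred <- predict_nn(nn, sp$val$sbp)
  cc <- ccf(pred$v1, sp$val$kin$v1, lag.max = 3, plot = FALSE)
  # the one-bin encoder lag is carried as a display delay; after removing
  # it, the prediction peak sits within one bin of zero
  expect_lte(abs(cc$lag[which.max(cc$acf)] - 1), 1)
})

test_that("gain calibration matches its definition", {
  t <- seq(0, 60, by = 0.05)
  # large amplitude keeps every rectified peak above the 1-sd threshold,
  # so the peak sets are hand-checkable
  actual <- 5 * cbind(sin(2 * pi * t / 3), cos(2 * pi * t / 4))
  gf <- compute_gain_factor(actual, 0.5 * actual)
  expect_equal(gf$gain, 2, tolerance = 1e-6)
  gf_id <- compute_gain_factor(actual, actual)
  expect_equal(gf_id$gain, 1, tolerance = 1e-6)
  expect_equal(unname(gf_id$median_offset), c(0, 0), tolerance = 0.05)
  # a pure offset: peak magnitudes average out (5.3 and 4.7), so the gain
  # stays 1 and the median offset recovers the shift
  gf_off <- compute_gain_factor(actual, actual + 0.3)
  expect_equal(gf_off$gain, 1, tolerance = 0.02)
  expect_equal(unname(gf_off$median_offset), c(0.3, 0.3), tolerance = 0.05)
  expect_error(compute_gain_factor(actual, actual * 0 + 1e-9), "peak")
})

test_that("gain correction is invariant to output rescaling", {
  t <- seq(0, 60, by = 0.05)
  actual <- cbind(sin(2 * pi * t / 3), cos(2 * pi * t / 3.7))
  pred <- 0.7 * actual + 0.05
  for (cc in c(0.2, 5)) {
    g1 <- compute_gain_factor(actual, pred)
    g2 <- compute_gain_factor(actual, pred * cc)
    expect_equal(g2$gain, g1$gain / cc, tolerance = 1e-8)
    expect_equal(pred * cc * g2$gain - rep(g2$median_offset, each = nrow(pred)),
                 pred * g1$gain - rep(g1$median_offset, each = nrow(pred)),
                 tolerance = 1e-8)
  }
})

test_that("triangular redistribution matches the closed-form target", {
  ses <- gaussian_velocity_session(n = 20000, seed = 16)
  idx <- redistribute_velocity_samples(ses$kin, 20000, seed = 17)
  expect_length(idx, 20000)
  v <- c(ses$kin$v1[idx], ses$kin$v2[idx])
  sig <- sd(c(ses$kin$v1, ses$kin$v2))
  expect_lt(ks_stat(v, function(x) triangular_cdf(x, sig)), 0.03)

  # input already triangular on [-4s, 4s] for a given scale s: the
  # importance weights are flat and the sample passes through unchanged
  set.seed(18)
  n <- 20000
  tri <- function(n, s) (runif(n) - runif(n)) * 4 * s
  kin_t <- data.frame(bin = 1:n, p1 = 0.5, p2 = 0.5,
                      v1 = tri(n, 0.25), v2 = tri(n, 0.25))
  idx_t <- redistribute_velocity_samples(kin_t, 20000, seed = 19,
                                         sigma = 0.25)
  vt <- c(kin_t$v1[idx_t], kin_t$v2[idx_t])
  expect_lt(ks_stat(vt, function(x) triangular_cdf(x, 0.25)), 0.02)

  expect_identical(redistribute_velocity_samples(ses$kin, 0), integer(0))
  kin0 <- data.frame(bin = 1:10, p1 = 0.5, p2 = 0.5, v1 = 0, v2 = 0)
  expect_error(redistribute_velocity_samples(kin0, 10), "degenerate")
})

test_that("nodal contributions decompose the raw output exactly", {
  # two-node toy with hand-computable contributions
  cfg <- nn_config(3, n_fc_layers = 2, hidden = 2, use_time_layer = FALSE,
                   use_regularization = FALSE)
  net <- build_network(cfg, seed = 20)
  net$params$W1 <- matrix(0, 3, 2)
  net$params$b1 <- c(1, 2)                  # hidden N = (1, 2) always
  net$params$W2 <- matrix(c(0.5, -0.25, 0.1, 0.1), 2, 2)
  net$params$b2 <- c(0, 0)
  net$trained <- TRUE
  y <- sbp_matrix(matrix(1, 3, 4))
  kin <- data.frame(bin = 1:4, p1 = 0.5, p2 = 0.5,
                    v1 = c(-1, 0, 1, 2), v2 = c(2, 1, 0, -1))
  rep_ <- nodal_contributions(net, y, kin)
  expect_equal(rep_$contribution[[1]][1, ], c(0.5, -0.5))
  expect_equal(rep_$raw_output[1, 1], 0)
  expect_identical(unname(rep_$node_sign[, 1]), c(1, -1))

  # exact decomposition on a real (trained) network
  enc <- make_encoder(8, 0.5, 0, 0.2, seed = 21)
  ses <- generate_session(task_config(), enc, 40, seed = 22)
  sp <- split_session(ses, 30)
  nn <- train_nn(sp$train, sp$val,
                 nn_config(8, n_fc_layers = 2, hidden = 16),
                 train_config(iterations = 150, learning_rate = 1e-3,
                              redistribute = FALSE, seed = 23))
  rp <- nodal_contributions(nn, sp$val$sbp, sp$val$kin)
  for (f in 1:2) {
    recon <- rowSums(rp$contribution[[f]]) + rp$bias[f]
    expect_lt(max(abs(recon - rp$raw_output[, f])), 1e-5)
  }
})

test_that("all-positive output weights class every node positive", {
  cfg <- nn_config(3, n_fc_layers = 2, hidden = 4, use_time_layer = FALSE,
                   use_regularization = FALSE)
  net <- build_network(cfg, seed = 24)
  net$params$W2 <- matrix(abs(net$params$W2), 4, 2)
  rep_ <- nodal_contributions(net, sbp_matrix(matrix(1, 3, 3)),
                              data.frame(bin = 1:3, p1 = 0, p2 = 0,
                                         v1 = c(-1, 0, 1), v2 = c(1, 0, -1)))
  expect_true(all(rep_$node_sign == 1))
})

test_that("the degenerate time-layer limit reproduces a lagged regression", {
  enc <- make_encoder(8, 0, 1, 0.05, seed = 25)
  # velocity-only tuning keeps the optimal lagged read-out separable across
  # (electrode, delay), which is the span of the rank-1 time layer
  enc$linear_weights[, 1:2] <- 0
  ses <- generate_session(task_config(), enc, 120, seed = 26)
  sp <- split_session(ses, 100)
  cfg <- nn_config(8, n_time_features = 1, n_fc_layers = 1,
                   use_regularization = FALSE, relu_identity = TRUE)
  nn <- train_nn(sp$train, sp$val, cfg,
                 train_config(iterations = 6000, learning_rate = 1e-2,
                              weight_decay = 0, redistribute = FALSE,
                              seed = 27))
  pred_nn <- predict_nn(nn, sp$val$sbp)
  # lagged OLS oracle: regress v_t on (y_t, y_{t-1}, y_{t-2})
  y_tr <- unclass(sp$train$sbp); n_tr <- ncol(y_tr)
  lagmat <- function(y) {
    n <- ncol(y)
    rbind(y, y[, c(1, seq_len(n - 1))], y[, c(1, 1, seq_len(n - 2))])
  }
  X <- cbind(1, t(lagmat(y_tr)))
  B <- qr.coef(qr(X), cbind(sp$train$kin$v1, sp$train$kin$v2))
  Xv <- cbind(1, t(lagmat(unclass(sp$val$sbp))))
  pred_ols <- Xv %*% B
  expect_gt(cor(pred_nn$v1, pred_ols[, 1]), 0.99)
  expect_gt(cor(pred_nn$v2, pred_ols[, 2]), 0.99)
})

test_that("training rejects mismatched channel counts", {
  fx <- linear_fixture()
  sp <- split_session(fx$ses, 30)
  expect_error(train_nn(sp$train, sp$val, nn_config(5),
                        train_config(iterations = 2)), "channel count")
})
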