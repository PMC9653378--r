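test_that("lag estimation recovers the encoder lag", {
  task <- task_config()
  for (lag in c(0L, 1L, 3L)) {
    enc <- make_encoder(16, 0.3, lag, 0.05, seed = 20 + lag)
    ses <- generate_session(task, enc, 30, seed = 30 + lag)
    expect_identical(estimate_optimal_lag(ses, 3), lag)
  }
  expect_error(estimate_optimal_lag(linear_fixture()$ses, 1e6), "shorter")
})

test_that("the transition matrix keeps its physical structure", {
  kf <- fit_kalman(noisy_fixture()$ses, lag_bins = 1)
  expect_identical(kf$A[1, ], c(1, 0, 0.05, 0, 0))
  expect_identical(kf$A[2, ], c(0, 1, 0, 0.05, 0))
  expect_identical(kf$A[5, ], c(0, 0, 0, 0, 1))
  expect_true(isSymmetric(kf$W) && isSymmetric(kf$Q))
  expect_true(all(eigen(kf$Q, only.values = TRUE)$values > -1e-8))
})

test_that("full-state regression recovers a noiseless linear encoder's map", {
  fx <- linear_fixture()
  kf <- fit_kalman(fx$ses, lag_bins = 0, drop_position = FALSE)
  C_true <- cbind(fx$enc$linear_weights, fx$enc$baseline)
  expect_lt(max(abs(kf$C - C_true) / pmax(abs(C_true), 1e-12)), 1e-6)
})

test_that("the velocity block recovers AR(1) dynamics", {
  set.seed(8)
  n <- 4000
  v1 <- as.numeric(stats::filter(rnorm(n, 0, 0.05), 0.9, "recursive"))
  v2 <- as.numeric(stats::filter(rnorm(n, 0, 0.05), 0.9, "recursive"))
  kin <- data.frame(bin = 1:n, p1 = 0.5 + cumsum(v1) * 0.05,
                    p2 = 0.5 + cumsum(v2) * 0.05, v1 = v1, v2 = v2)
  enc <- make_encoder(8, 0, 0, 0.05, seed = 8)
  ses <- session_bundle(encode_sbp(kin, enc, seed = 8), kin,
                        data.frame(trial = 1L, target1 = 0.5, target2 = 0.5,
                                   start_bin = 1L, target_onset_bin = 1L,
                                   acquire_bin = NA_integer_, end_bin = n,
                                   success = FALSE, d1 = 0, d2 = 0,
                                   excluded = FALSE),
                        mode = "manipulandum")
  kf <- fit_kalman(ses, lag_bins = 0)
  expect_lt(max(abs(kf$A[3:4, 3:4] - 0.9 * diag(2))), 0.02)
})

test_that("rank-deficient regressors raise a named singular-fit error", {
  fx <- linear_fixture()
  ses <- fx$ses
  ses$kin$v2 <- ses$kin$v1  # collinear fingers
  expect_error(fit_kalman(ses, lag_bins = 0), "singular fit")
})

test_that("a velocity-dead filter decodes constant positions", {
  kf <- fit_kalman(noisy_fixture()$ses, lag_bins = 1)
  kf$C[, 3:4] <- 0
  kf$W[3:4, 3:4] <- 0
  dec <- decode_kalman(kf, noisy_fixture()$ses$sbp, p0 = c(0.3, 0.7))
  expect_true(all(dec$v1 == 0) && all(dec$v2 == 0))
  expect_true(all(dec$p1 == 0.3) && all(dec$p2 == 0.7))
})

test_that("self-decode on a noiseless linear session is near perfect", {
  fx <- linear_fixture()
  kf <- fit_kalman(fx$ses, lag_bins = 0)
  dec <- decode_kalman(kf, fx$ses$sbp)
  r <- velocity_correlation(dec, fx$ses$kin)
  expect_gt(min(r$per_finger), 0.99)
})

test_that("decoded position exactly integrates decoded velocity", {
  ses <- noisy_fixture()$ses
  kf <- fit_kalman(ses, lag_bins = 1)
  dec <- decode_kalman(kf, ses$sbp)
  n <- nrow(dec)
  expect_lt(max(abs(diff(dec$p1) - dec$v1[-n] * 0.05)), 1e-12)
  expect_lt(max(abs(diff(dec$p2) - dec$v2[-n] * 0.05)), 1e-12)
})

test_that("the Kalman gain converges to a fixed point", {
  ses <- noisy_fixture()$ses
  kf <- fit_kalman(ses, lag_bins = 1)
  dec <- decode_kalman(kf, ses$sbp)
  gp <- attr(dec, "gain_path")
  expect_true(all(gp[200:length(gp)] < 1e-10))
})

test_that("time-lagged-feature observations fit and decode", {
  ses <- noisy_fixture()$ses
  kf3 <- fit_kalman(ses, lag_bins = 1, n_feature_lags = 3)
  expect_equal(nrow(kf3$C), 3 * nrow(ses$sbp))
  dec <- decode_kalman(kf3, ses$sbp)
  expect_gt(lag_aligned_corr(dec, ses$kin, 1), 0.5)
  expect_error(fit_kalman(ses, n_feature_lags = 2), "1 or 3")
})

test_that("ridge regression matches OLS at lambda 0 and shrinks to zero", {
  ses <- noisy_fixture()$ses
  r0 <- fit_ridge(ses, 0)
  X <- cbind(1, t(unclass(ses$sbp)))
  B_ols <- qr.coef(qr(X), cbind(ses$kin$v1, ses$kin$v2))
  expect_lt(max(abs(r0$B - B_ols[-1, ])), 1e-8)
  rInf <- fit_ridge(ses, 1e12)
  expect_lt(max(abs(rInf$B)), 1e-6)
  fx <- linear_fixture()
  rr <- fit_ridge(fx$ses, 1e-4)
  pr <- predict(rr, fx$ses$sbp)
  expect_gt(velocity_correlation(pr, fx$ses$kin)$mean, 0.99)
})

test_that("restricted fits qualify the expected bins", {
  # all-positive velocities: KF+ keeps every bin
  n <- 600
  set.seed(13)
  v1 <- abs(rnorm(n, 0.3, 0.2)); v2 <- abs(rnorm(n, 0.3, 0.2))
  kin <- data.frame(bin = 1:n, p1 = pmin(cumsum(v1) * 0.05, 1),
                    p2 = pmin(cumsum(v2) * 0.05, 1), v1 = v1, v2 = v2)
  enc <- make_encoder(8, 0, 0, 0.1, seed = 13)
  ses <- session_bundle(encode_sbp(kin, enc, seed = 13), kin,
                        data.frame(trial = 1L, target1 = 1, target2 = 1,
                                   start_bin = 1L, target_onset_bin = 1L,
                                   acquire_bin = NA_integer_, end_bin = n,
                                   success = FALSE, d1 = 0, d2 = 0,
                                   excluded = FALSE),
                        mode = "manipulandum")
  kp <- fit_restricted_kalman(ses, "positive", lag_bins = 0)
  expect_equal(attr(kp, "retained_fraction"), 1)

  # symmetric Gaussian velocities: both sides keep ~ P(V > -sigma/2)^2
  ses_g <- gaussian_velocity_session(n = 6000, seed = 14)
  kp_g <- fit_restricted_kalman(ses_g, "positive", lag_bins = 0)
  kn_g <- fit_restricted_kalman(ses_g, "negative", lag_bins = 0)
  expected <- pnorm(0.5)^2
  expect_lt(abs(attr(kp_g, "retained_fraction") - expected), 0.03)
  expect_lt(abs(attr(kn_g, "retained_fraction") - expected), 0.03)

  expect_error(fit_restricted_kalman(ses_g, "positive", lag_bins = 0) -> x,
               NA)
  short <- session_bundle(
    sbp_matrix(unclass(ses_g$sbp)[, 1:120]), ses_g$kin[1:120, ],
    transform(ses_g$trials, end_bin = 120L), mode = "manipulandum")
  short$kin$v1 <- abs(short$kin$v1)
  short$kin$v2 <- -abs(short$kin$v2) - 2  # nothing qualifies as positive
  expect_error(fit_restricted_kalman(short, "positive", lag_bins = 0),
               "too few qualifying")
})

test_that("restriction nesting: KF+ equals the full fit when all bins qualify", {
  n <- 600
  set.seed(15)
  v1 <- abs(rnorm(n, 0.3, 0.1)); v2 <- abs(rnorm(n, 0.3, 0.1))
  kin <- data.frame(bin = 1:n, p1 = 0.5 + 0.3 * sin(1:n / 20),
                    p2 = 0.5 + 0.3 * cos(1:n / 17), v1 = v1, v2 = v2)
  enc <- make_encoder(8, 0, 0, 0.05, seed = 15)
  ses <- session_bundle(encode_sbp(kin, enc, seed = 15), kin,
                        data.frame(trial = 1L, target1 = 1, target2 = 1,
                                   start_bin = 1L, target_onset_bin = 1L,
                                   acquire_bin = NA_integer_, end_bin = n,
                                   success = FALSE, d1 = 0, d2 = 0,
                                   excluded = FALSE),
                        mode = "manipulandum")
  kp <- fit_restricted_kalman(ses, "positive", lag_bins = 0)
  kf <- fit_kalman(ses, lag_bins = 0, drop_position = FALSE,
                   position_uncertainty = TRUE)
  expect_equal(kp$C, kf$C, tolerance = 1e-10)
})
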