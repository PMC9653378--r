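test_that("target generation respects range, separation and non-overlap", {
  task <- task_config(target_range = 0.95)
  s <- fingerbmi:::make_stream(1, "targets")
  prev <- NULL
  for (i in 1:2000) {
    tg <- generate_targets(task, prev, s)
    expect_true(all(tg >= 0.025 & tg <= 0.975))
    expect_lte(abs(tg[1] - tg[2]), 0.5)
    if (!is.null(prev)) {
      expect_true(all(abs(tg - prev) >= task$target_width))
    }
    prev <- tg
  }
  s1 <- fingerbmi:::make_stream(9, "targets")
  s2 <- fingerbmi:::make_stream(9, "targets")
  expect_identical(generate_targets(task, NULL, s1),
                   generate_targets(task, NULL, s2))
  # impossible geometry trips the resample cap
  tiny <- task_config(target_range = 0.01, target_width = 0.5,
                      max_target_separation = 1)
  expect_error(generate_targets(tiny, c(0.5, 0.5), s1), "cap exceeded")
})

test_that("the zero decoder times out every trial", {
  task <- task_config(target_range = 0.95, trial_timeout = 2000)
  enc <- make_encoder(6, 0.3, 0, 0.1, seed = 1)
  run <- run_closed_loop("zero", enc, task, 5, seed = 2)
  expect_equal(sum(run$trials$success), 0)
  expect_true(all((run$trials$end_bin - run$trials$target_onset_bin + 1) ==
                    task$trial_timeout / task$bin_size))
  expect_true(all(run$kin$v1 == 0))
})

test_that("the oracle decoder acquires at the kinematically predicted time", {
  task <- task_config(target_range = 0.95)
  user <- user_config(gain = 100, v_max = 0.5, smooth_tau = 0,
                      reaction_delay = 0, jitter_sd = 0)
  enc <- make_encoder(6, 0.3, 0, 0.1, seed = 3)
  run <- run_closed_loop("oracle", enc, task, 8, seed = 4, user = user)
  expect_true(all(run$trials$success))
  S <- task$target_width / 2
  for (i in seq_len(nrow(run$trials))) {
    tr <- run$trials[i, ]
    t_pred <- max(max(tr$d1, tr$d2) - S, 0) / 0.5 + task$hold_time_test / 1000
    t_obs <- (tr$end_bin - tr$target_onset_bin + 1) * task$bin_size / 1000
    expect_lte(abs(t_obs - t_pred), task$bin_size / 1000 + 1e-9)
  }
})

test_that("closed-loop runs are reproducible and kinematically consistent", {
  task <- task_config(target_range = 0.95, trial_timeout = 3000)
  enc <- make_encoder(12, 0.5, 1, 0.3, seed = 5)
  ses <- generate_session(task_config(), enc, 50, seed = 6)
  kf <- fit_kalman(ses, lag_bins = 1)
  r1 <- run_closed_loop(kf, enc, task, 8, seed = 7)
  r2 <- run_closed_loop(kf, enc, task, 8, seed = 7)
  expect_identical(r1$kin, r2$kin)
  expect_identical(unclass(r1$sbp), unclass(r2$sbp))
  expect_identical(r1$trials, r2$trials)

  # positions stay in range; increments equal decoded velocity x dt where
  # no clipping occurred
  p <- cbind(r1$kin$p1, r1$kin$p2)
  v <- cbind(r1$kin$v1, r1$kin$v2)
  expect_true(all(p >= 0 & p <= 1))
  n <- nrow(p)
  interior <- p[-1, ] > 0 & p[-1, ] < 1
  dp <- p[-1, ] - p[-n, ]
  expect_lt(max(abs((dp - v[-n, ] * 0.05))[interior]), 1e-12)

  # dwell accounting for successful trials
  hold_bins <- task$hold_time_test / task$bin_size
  w2 <- task$target_width / 2
  for (i in which(r1$trials$success)) {
    tr <- r1$trials[i, ]
    expect_gte(tr$end_bin - tr$acquire_bin + 1, hold_bins)
    idx <- tr$acquire_bin:tr$end_bin
    expect_true(all(abs(r1$kin$p1[idx] - tr$target1) <= w2 &
                      abs(r1$kin$p2[idx] - tr$target2) <= w2))
  }
})

test_that("the oracle closed loop equals the open-loop user bin-for-bin", {
  task <- task_config(hold_time_train = 500)  # same hold in both modes
  enc <- make_encoder(10, 0.4, 1, 0.2, seed = 8)
  open <- generate_session(task, enc, 10, seed = 9)
  closed <- run_closed_loop("oracle", enc, task, 10, seed = 9)
  expect_equal(closed$kin$p1, open$kin$p1, tolerance = 1e-12)
  expect_equal(closed$kin$v1, open$kin$v1, tolerance = 1e-12)
  expect_identical(unclass(closed$sbp), unclass(open$sbp))
  expect_equal(closed$trials$end_bin, open$trials$end_bin)
})

test_that("alternation schedules follow the protocol", {
  expect_identical(ab_alternation_schedule(c("A", "B"), 3, "AB")$decoder,
                   c("A", "B", "A"))
  expect_identical(ab_alternation_schedule(c("A", "B"), 4, "BA")$decoder,
                   c("B", "A", "B", "A"))
  plan <- ab_alternation_schedule(c("RN", "RK"), 2, "AB",
                                  trials_per_block = 120, n_excluded = 50)
  expect_true(all(plan$n_excluded == 50))
  expect_error(ab_alternation_schedule("A", 2), "2 decoders")
})

test_that("ReFIT rescues a sign-corrupted neural network decoder", {
  task <- task_config(target_range = 0.95, trial_timeout = 6000)
  enc <- make_encoder(16, 0.5, 0, 0.2, seed = 10)
  ses <- generate_session(task_config(), enc, 80, seed = 11)
  sp <- split_session(ses, 64)
  nn <- train_nn(sp$train, sp$val,
                 nn_config(16, n_fc_layers = 2, hidden = 48),
                 train_config(iterations = 600, learning_rate = 1e-3,
                              weight_decay = 2e-3, redistribute = FALSE,
                              seed = 12))
  bad <- nn
  bad$gain <- -bad$gain  # velocity readout negated
  run_bad <- run_closed_loop(bad, enc, task, 25, seed = 13)
  rn <- refit_nn(bad, run_bad,
                 tc = train_config(iterations = 400, learning_rate = 1e-3,
                                   weight_decay = 2e-3, redistribute = FALSE,
                                   seed = 14),
                 val = sp$val)
  eval_bad <- run_closed_loop(bad, enc, task, 25, seed = 15)
  eval_rn <- run_closed_loop(rn, enc, task, 25, seed = 15)
  expect_gt(mean(eval_rn$trials$success), mean(eval_bad$trials$success))
})

test_that("flip-rule targets never flip zeros and refit demands targets", {
  kin <- data.frame(bin = 1:3, p1 = c(0.2, 0.2, 0.2), p2 = 0.8,
                    v1 = c(0, -0.3, 0.3), v2 = 0)
  tr <- data.frame(trial = 1L, target1 = 0.6, target2 = 0.4, start_bin = 1L,
                   target_onset_bin = 1L, acquire_bin = NA_integer_,
                   end_bin = 3L, success = TRUE, d1 = 0.4, d2 = 0.4,
                   excluded = FALSE)
  out <- fingerbmi:::nn_flip_targets(kin, tr)
  expect_equal(out$v1, c(0, 0.3, 0.3))  # zero untouched, wrong sign flipped
  fx <- linear_fixture()
  nn <- build_network(nn_config(16, n_fc_layers = 2, hidden = 8), seed = 1)
  expect_error(refit_nn(nn, fx$ses), "brain_control")
})
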