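trial_row <- function(d1, d2, onset = 1L, end = 20L, success = TRUE,
                      acquire = NA_integer_) {
  data.frame(trial = 1L, target1 = 0.5, target2 = 0.5, start_bin = onset,
             target_onset_bin = onset, acquire_bin = acquire, end_bin = end,
             success = success, d1 = d1, d2 = d2, excluded = FALSE)
}

test_that("throughput evaluates the Fitts formula exactly", {
  task <- task_config()  # S = 0.075
  # one active finger, D = 0.375, t_acq = 1 s -> log2(3)
  tp <- fitts_throughput(trial_row(0.375, 0.075, end = 20L), task)
  expect_equal(tp$per_trial, log2(3), tolerance = 1e-12)
  # both fingers at the radius -> 0 bits regardless of time
  tp0 <- fitts_throughput(trial_row(0.075, 0.075, end = 100L), task)
  expect_equal(tp0$per_trial, 0)
  # two fingers, D = 0.225 each, t_acq = 2 s -> 1 bit/s
  tp2 <- fitts_throughput(trial_row(0.225, 0.225, end = 40L), task)
  expect_equal(tp2$per_trial, 1, tolerance = 1e-12)
})

test_that("throughput is monotone in difficulty and time", {
  task <- task_config()
  base <- fitts_throughput(trial_row(0.3, 0.3, end = 20L), task)$per_trial
  slower <- fitts_throughput(trial_row(0.3, 0.3, end = 30L), task)$per_trial
  harder <- fitts_throughput(trial_row(0.4, 0.3, end = 20L), task)$per_trial
  expect_lt(slower, base)
  expect_gt(harder, base)
  expect_gt(base, 0)
  # unsuccessful trials are excluded
  tr <- rbind(trial_row(0.3, 0.3), trial_row(0.4, 0.4, success = FALSE))
  expect_equal(fitts_throughput(tr, task)$n, 1)
})

test_that("trial timing splits acquisition into entry and dwell", {
  task <- task_config()
  hold_bins <- task$hold_time_test / task$bin_size  # 10
  n <- 30L
  # enters the target at bin 21 and stays to the end
  p1 <- c(rep(0, 20), rep(0.5, 10))
  kin <- data.frame(bin = 1:n, p1 = p1, p2 = p1, v1 = 0, v2 = 0)
  ses <- session_bundle(NULL, kin,
                        trial_row(0.5, 0.5, end = n, acquire = 21L),
                        mode = "brain_control")
  tt <- trial_times(ses$trials, ses, task)
  expect_equal(tt$dwell_time, task$hold_time_test)
  expect_equal(tt$acquisition_time, n * task$bin_size)
  expect_equal(tt$acquisition_time, tt$time_to_target + tt$dwell_time)

  # one excursion out of the target: only the final stay counts as dwell
  p2 <- c(rep(0, 10), rep(0.5, 5), rep(0, 5), rep(0.5, 10))
  kin2 <- data.frame(bin = 1:n, p1 = p2, p2 = p2, v1 = 0, v2 = 0)
  ses2 <- session_bundle(NULL, kin2,
                         trial_row(0.5, 0.5, end = n, acquire = 21L),
                         mode = "brain_control")
  tt2 <- trial_times(ses2$trials, ses2, task)
  expect_equal(tt2$dwell_time, task$hold_time_test)
  tt2f <- trial_times(ses2$trials, ses2, task, first_entry = TRUE)
  expect_equal(tt2f$time_to_target, 10 * task$bin_size)
})

test_that("velocity correlation behaves like Pearson r", {
  x <- data.frame(v1 = c(1, 2, 3, 4), v2 = c(4, 3, 2, 1))
  y <- data.frame(v1 = c(1, 2, 3, 5), v2 = c(4, 3, 2, 1))
  expect_equal(velocity_correlation(x, x)$per_finger, c(1, 1))
  xn <- x; xn$v1 <- -x$v1; xn$v2 <- -x$v2
  expect_equal(velocity_correlation(xn, x)$per_finger, c(-1, -1))
  expect_equal(velocity_correlation(y, x)$per_finger[1], 0.9827, tolerance = 1e-4)
  # invariance under positive affine maps
  xs <- x; xs$v1 <- 3 * x$v1 + 2; xs$v2 <- 0.1 * x$v2 - 5
  expect_equal(velocity_correlation(xs, x)$per_finger, c(1, 1))
  bad <- x; bad$v1 <- 0
  expect_error(velocity_correlation(bad, x), "constant")
})

test_that("the mean speed profile applies the zero-fill rule", {
  task <- task_config()
  n <- 100L
  kin <- data.frame(bin = 1:n, p1 = 0.5, p2 = 0.5, v1 = 0.5, v2 = 0.5)
  tr <- rbind(trial_row(0.3, 0.3, onset = 1L, end = 20L),     # 1000 ms
              trial_row(0.3, 0.3, onset = 21L, end = 40L))
  ses <- session_bundle(NULL, kin, tr, mode = "brain_control")
  prof <- mean_speed_profile(ses, task)
  expect_length(prof$mean, 40)
  expect_equal(prof$mean[1:20], rep(0.5, 20))
  expect_equal(prof$mean[21:40], rep(0, 20))  # zero-filled past completion
  expect_equal(prof$sem, rep(0, 40))          # identical trials
  expect_equal(prof$peak, 0.5)
})

test_that("the binned velocity curve is normalized at zero true velocity", {
  set.seed(33)
  n <- 5000
  actual <- cbind(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5))
  pred <- 0.8 * actual + 0.2 * cbind(rnorm(n, 0, 0.3), rnorm(n, 0, 0.3))
  cv <- binned_velocity_curve(pred, actual)
  expect_s3_class(cv, "velocity_curve")
  expect_true(all(diff(cv$center) == 0.5))
  # the enforced constraint: rescaled zero-bin predictions have sd 0.5
  sig <- apply(actual, 2, sd)
  anorm <- c(abs(sweep(actual, 2, sig, `/`)))
  scale <- 0.5 / sd(c(pred)[anorm < 0.25])
  expect_equal(sd(c(pred)[anorm < 0.25] * scale), 0.5, tolerance = 1e-12)
  # identity predictions give a monotone increasing curve
  cvi <- binned_velocity_curve(actual, actual)
  expect_true(all(diff(cvi$mean_pred[cvi$n > 20]) > 0))
  expect_error(binned_velocity_curve(pred + 100, actual, zero_frac = 1e-9),
               "zero bin")
})

test_that("t-test wrappers reproduce hand-computed statistics", {
  r1 <- t_tests(c(1, 2, 3), c(1, 2, 3), "two_sample")
  expect_equal(r1$t, 0)
  expect_equal(r1$p, 1)
  r2 <- t_tests(c(1, 2, 3), 2, "one_sample")
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)
  r3 <- t_tests(c(2, 4, 6), 0, "one_sample")
  expect_equal(r3$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r3$p, 0.0742, tolerance = 1e-3)
  expect_equal(r3$df, 2)
  expect_error(t_tests(1, 0, "one_sample"), "at least 2")
})
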