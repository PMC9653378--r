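# Small fixtures shared across test files, built once per test run.
.fix <- new.env(parent = emptyenv())

fix_cached <- function(name, expr) {
  if (!exists(name, envir = .fix)) assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

# Noiseless, lag-0, purely linear encoder + short session: the exact-recovery
# workhorse.
linear_fixture <- function() fix_cached("linear", {
  enc <- make_encoder(16, nonlinearity_mix = 0, lag_bins = 0,
                      noise_scale = 0, seed = 1)
  ses <- generate_session(task_config(), enc, 40, seed = 2)
  list(enc = enc, ses = ses)
})

# Mid-noise saturating encoder session (the standard study condition).
noisy_fixture <- function() fix_cached("noisy", {
  enc <- make_encoder(24, nonlinearity_mix = 0.8, lag_bins = 1,
                      noise_scale = 0.35, seed = 3)
  ses <- generate_session(task_config(), enc, 60, seed = 4)
  list(enc = enc, ses = ses)
})

# Hand-built session with Gaussian velocities (no task structure); useful
# where a known velocity distribution is the point.
gaussian_velocity_session <- function(n = 4000, seed = 5, sd_v = 0.5) {
  set.seed(seed)
  v1 <- rnorm(n, 0, sd_v); v2 <- rnorm(n, 0, sd_v)
  p1 <- 0.5 + cumsum(v1) * 0.05; p2 <- 0.5 + cumsum(v2) * 0.05
  kin <- data.frame(bin = seq_len(n), p1 = p1, p2 = p2, v1 = v1, v2 = v2)
  enc <- make_encoder(12, 0, 0, 0.1, seed = seed)
  sbp <- encode_sbp(kin, enc, seed = seed)
  trials <- data.frame(trial = 1L, target1 = 0.5, target2 = 0.5,
                       start_bin = 1L, target_onset_bin = 1L,
                       acquire_bin = NA_integer_, end_bin = n,
                       success = FALSE, d1 = 0, d2 = 0, excluded = FALSE)
  session_bundle(sbp, kin, trials, mode = "manipulandum")
}

# Symmetric triangular CDF on [-4s, 4s] peaked at 0 (independent oracle for
# the velocity-redistribution checks).
triangular_cdf <- function(v, s) {
  u <- pmin(pmax(v / (4 * s), -1), 1)
  ifelse(u < 0, (1 + u)^2 / 2, 1 - (1 - u)^2 / 2)
}

ks_stat <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n))
}

# Naive re-implementation of the SBP front end: direct-form difference
# equation applied forward and backward, loop binning. Independent of the
# vectorized pipeline; shares only the Butterworth coefficients.
naive_sbp <- function(x, fs, band = c(300, 1000), order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  b <- bf$b; a <- bf$a
  run <- function(x) {
    n <- length(x)
    y <- numeric(n)
    for (t in seq_len(n)) {
      acc <- 0
      for (k in seq_along(b)) if (t - k + 1 >= 1) acc <- acc + b[k] * x[t - k + 1]
      for (k in 2:length(a)) if (t - k + 1 >= 1) acc <- acc - a[k] * y[t - k + 1]
      y[t] <- acc / a[1]
    }
    y
  }
  # same odd-reflection padding as the pipeline, applied longhand
  n <- length(x)
  np <- min(n - 1L, max(as.integer(round(0.1 * n)), 100L))
  head_pad <- numeric(np); tail_pad <- numeric(np)
  for (i in seq_len(np)) {
    head_pad[i] <- 2 * x[1] - x[np + 2L - i]
    tail_pad[i] <- 2 * x[n] - x[n - i]
  }
  xx <- c(head_pad, x, tail_pad)
  y <- rev(run(rev(run(xx))))
  y <- y[(np + 1L):(np + n)]
  y <- y[seq(1, length(y), by = as.integer(fs / 2000))]
  per <- 100L
  nb <- length(y) %/% per
  out <- numeric(nb)
  for (i in seq_len(nb)) {
    acc <- 0
    for (j in 1:per) acc <- acc + abs(y[(i - 1) * per + j])
    out[i] <- acc / per
  }
  out
}

# Mean per-finger correlation between a decode and true kinematics, with the
# decoder's display lag removed.
lag_aligned_corr <- function(dec, kin, lag) {
  n <- nrow(dec)
  if (lag > 0) {
    mean(c(cor(dec$v1[(1 + lag):n], kin$v1[1:(n - lag)]),
           cor(dec$v2[(1 + lag):n], kin$v2[1:(n - lag)])))
  } else {
    mean(c(cor(dec$v1, kin$v1), cor(dec$v2, kin$v2)))
  }
}
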