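# The two simulation studies shared by the acceptance tests, computed once
# and cached. Study conditions (fixed up front; see the methods vignette):
# 64-channel encoder with strongly rectified-saturating velocity tuning
# (nonlinearity_mix 0.8), one-bin physiological lag, per-channel noise sd
# 0.35; offline sessions of 400 training + 100 validation trials; network
# training at 1000 Adam iterations with step size 5e-4 and weight decay
# 2e-3 (the reduced-iteration recipe).

study_tc <- function(seed, iterations = 1000L) {
  train_config(iterations = iterations, learning_rate = 5e-4,
               weight_decay = 2e-3, seed = seed)
}

study_encoder <- function(seed) {
  make_encoder(64, nonlinearity_mix = 0.8, lag_bins = 1L,
               noise_scale = 0.35, seed = seed)
}

offline_study <- function() fix_cached("offline_study", {
  task <- task_config()
  lapply(1:5, function(s) {
    enc <- study_encoder(s)
    ses <- generate_session(task, enc, 500, seed = 100 + s)
    sp <- split_session(ses, 400)
    kf <- fit_kalman(sp$train, lag_bins = 1)
    dk <- decode_kalman(kf, sp$val$sbp)
    corr <- c(kf = lag_aligned_corr(dk, sp$val$kin, 1))
    variants <- list(
      nn4t = nn_config(64, n_fc_layers = 4),
      nn2t = nn_config(64, n_fc_layers = 2),
      nn2 = nn_config(64, n_fc_layers = 2, use_time_layer = FALSE),
      nn2nr = nn_config(64, n_fc_layers = 2, use_time_layer = FALSE,
                        use_regularization = FALSE))
    models <- list()
    for (nm in names(variants)) {
      m <- train_nn(sp$train, sp$val, variants[[nm]], study_tc(s))
      corr[nm] <- m$val_correlation
      if (nm == "nn4t") models$nn4t <- m
    }
    list(seed = s, corr = corr, nn4t = models$nn4t, kf = kf,
         kf_decode = dk, val = sp$val)
  })
})

closed_loop_study <- function() fix_cached("closed_loop_study", {
  task_tr <- task_config()
  task_cl <- task_config(target_range = 0.95)
  lapply(1:5, function(s) {
    enc <- study_encoder(s)
    ses <- generate_session(task_tr, enc, 250, seed = 300 + s)
    sp <- split_session(ses, 200)
    kf <- fit_kalman(sp$train, lag_bins = 1)
    nn <- train_nn(sp$train, sp$val, nn_config(64, n_fc_layers = 4),
                   study_tc(s))
    run_kf <- run_closed_loop(kf, enc, task_cl, 100, seed = 400 + s)
    run_nn <- run_closed_loop(nn, enc, task_cl, 100, seed = 500 + s)
    rk <- refit_kalman(run_kf, "rotate", lag_bins = 1)
    rn <- refit_nn(nn, run_nn,
                   tc = train_config(iterations = 500L,
                                     learning_rate = 5e-4,
                                     weight_decay = 2e-3,
                                     redistribute = FALSE, seed = s),
                   val = sp$val)
    tp <- sapply(list(KF = kf, RK = rk, NN = nn, RN = rn), function(d) {
      ev <- run_closed_loop(d, enc, task_cl, 100, seed = 600 + s)
      fitts_throughput(ev$trials, task_cl)$mean
    })
    list(seed = s, throughput = tp)
  })
})
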