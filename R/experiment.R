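#' Run a full simulated decoding experiment
#'
#' Orchestrates the standard protocol end-to-end: generate an open-loop
#' (manipulandum-control) training session, fit the Kalman filter and train
#' the neural network, run a closed-loop calibration block with each,
#' ReFIT-retrain both, evaluate all four decoders in alternating blocks,
#' and assemble a performance report (throughput, trial times, success
#' counts).
#'
#' @param config a named list:
#'   `n_channels`, `nonlinearity_mix`, `lag_bins`, `noise_scale` (encoder);
#'   `n_train_trials`, `n_val_trials`, `n_calib_trials`, `n_eval_trials`;
#'   `nn_iterations`, `nn_refit_iterations`, `learning_rate`;
#'   `schedule_order` ("AB"/"BA"), `n_excluded`; `seed`; optional `out`
#'   directory.
#' @return a report list (invisibly writes `report.json` and sessions when
#'   `config$out` is set).
#' @export
run_experiment <- function(config) {
  cf <- utils::modifyList(list(
    n_channels = 32L, nonlinearity_mix = 0.8, lag_bins = 1L,
    noise_scale = 0.5, n_train_trials = 200L, n_val_trials = 50L,
    n_calib_trials = 60L, n_eval_trials = 60L,
    nn_iterations = 800L, nn_refit_iterations = 300L,
    learning_rate = 1e-3, schedule_order = "AB", n_excluded = 1L,
    seed = 1L, out = NULL), config)
  seed <- as.integer(cf$seed)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  task_train <- task_config(target_range = 1.0)
  task_test <- task_config(target_range = 0.95)
  enc <- make_encoder(cf$n_channels, cf$nonlinearity_mix, cf$lag_bins,
                      cf$noise_scale, seed = seed)

  say("stage simulate: %d + %d open-loop trials",
      cf$n_train_trials, cf$n_val_trials)
  ses <- generate_session(task_train, enc,
                          cf$n_train_trials + cf$n_val_trials, seed = seed)
  sp <- split_session(ses, cf$n_train_trials)

  say("stage train-kf")
  lag <- estimate_optimal_lag(sp$train, 3)
  kf <- fit_kalman(sp$train, lag_bins = lag)
  say("stage train-nn: %d iterations", cf$nn_iterations)
  tc <- train_config(iterations = cf$nn_iterations,
                     learning_rate = cf$learning_rate,
                     seed = seed)
  nn <- train_nn(sp$train, sp$val, nn_config(cf$n_channels), tc)

  say("stage closed-loop calibration: %d trials each", cf$n_calib_trials)
  run_kf <- run_closed_loop(kf, enc, task_test, cf$n_calib_trials,
                            seed = seed + 101L)
  run_nn <- run_closed_loop(nn, enc, task_test, cf$n_calib_trials,
                            seed = seed + 102L)

  say("stage refit")
  rk <- refit_kalman(run_kf, method = "rotate", lag_bins = lag)
  rn <- refit_nn(nn, run_nn,
                 tc = train_config(iterations = cf$nn_refit_iterations,
                                   learning_rate = cf$learning_rate,
                                   redistribute = FALSE, seed = seed),
                 val = sp$val)

  decoders <- list(KF = kf, RK = rk, NN = nn, RN = rn)
  say("stage evaluate: %d trials per decoder", cf$n_eval_trials)
  plan <- ab_alternation_schedule(c("KF", "NN"), 2, cf$schedule_order,
                                  cf$n_eval_trials, cf$n_excluded)
  report <- list(seed = seed, schedule = plan, decoders = list())
  for (nm in names(decoders)) {
    run <- run_closed_loop(decoders[[nm]], enc, task_test, cf$n_eval_trials,
                           seed = seed + 200L)
    tr <- run$trials
    tr$excluded[seq_len(min(cf$n_excluded, nrow(tr)))] <- TRUE
    tp <- fitts_throughput(tr, task_test)
    tt <- trial_times(tr, run, task_test)
    report$decoders[[nm]] <- list(
      throughput_bps = tp$mean, throughput_sem = tp$sem,
      successful = sum(tr$success), total = nrow(tr),
      excluded = sum(tr$excluded),
      acquisition_ms = mean(tt$acquisition_time[tt$success]),
      time_to_target_ms = mean(tt$time_to_target[tt$success]),
      dwell_ms = mean(tt$dwell_time[tt$success]))
    say("  %s: %.3f bps, %d/%d successful", nm, tp$mean,
        sum(tr$success), nrow(tr))
    if (!is.null(cf$out)) save_session(run, file.path(cf$out, paste0("run_", nm)))
  }
  report$log <- log_lines
  if (!is.null(cf$out)) {
    dir.create(cf$out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cf$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    save_model(kf, file.path(cf$out, "kf.model"))
    save_model(nn, file.path(cf$out, "nn.model"))
  }
  invisible(report)
}
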