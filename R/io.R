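SESSION_FORMAT_VERSION <- 1L
MODEL_FORMAT_VERSION <- 1L

num_fmt <- function(x) sprintf("%.17g", x)  # round-trips doubles exactly

write_num_csv <- function(m, path, col_names) {
  m <- as.matrix(m)
  lines <- c(paste(col_names, collapse = ","),
             apply(m, 1, function(r) paste(num_fmt(r), collapse = ",")))
  writeLines(lines, path)
}

read_num_csv <- function(path, n_cols = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("parse error in ", path, ": empty file")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (is.null(n_cols)) n_cols <- length(header)
  if (length(lines) == 1) {
    return(list(header = header,
                values = matrix(numeric(0), 0, n_cols)))
  }
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(vapply(body, length, integer(1)) != n_cols)
  if (length(bad) > 0)
    stop("parse error in ", basename(path), " at row ", bad[1] + 1,
         ": expected ", n_cols, " fields")
  cells <- unlist(body)
  vals <- suppressWarnings(
    matrix(as.numeric(cells), length(body), n_cols, byrow = TRUE))
  # "NA" is a legal cell (e.g. acquire_bin of failed trials); anything else
  # that fails to parse is an error located by row
  bad_cell <- is.na(vals) &
    matrix(cells != "NA", length(body), n_cols, byrow = TRUE)
  if (any(bad_cell))
    stop("parse error in ", basename(path), " at row ",
         which(rowSums(bad_cell) > 0)[1] + 1, ": non-numeric field")
  list(header = header, values = vals)
}

# Cheap order-sensitive content checksum for numeric payloads.
content_checksum <- function(xs) {
  v <- unlist(lapply(xs, as.numeric), use.names = FALSE)
  k <- seq_along(v) %% 97 + 1
  sprintf("%d:%.10e:%.10e", length(v), sum(v * k), sum(abs(v)))
}

#' Save / load a session bundle
#'
#' On-disk form: a directory with `sbp.csv` (header `ch1..chN`, one row per
#' 50-ms bin), `kinematics.csv` (`bin, p1, p2, v1, v2`), `trials.csv`,
#' optional `intended_kinematics.csv`, and `meta.json` (format version, bin
#' size, mode, seed, channel mask, descriptions). Numbers are written with
#' 17 significant digits so the round-trip is lossless.
#'
#' @param session a `session_bundle`.
#' @param path directory to create/read.
#' @return `save_session` returns `path` invisibly; `load_session` a
#'   `session_bundle`.
#' @export
save_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  y <- unclass(session$sbp)
  write_num_csv(t(y), file.path(path, "sbp.csv"),
                paste0("ch", seq_len(nrow(y))))
  write_num_csv(as.matrix(session$kin), file.path(path, "kinematics.csv"),
                names(session$kin))
  tr <- session$trials
  tr_num <- as.matrix(transform(tr, success = as.numeric(success),
                                excluded = as.numeric(excluded)))
  write_num_csv(tr_num, file.path(path, "trials.csv"), colnames(tr_num))
  if (!is.null(session$kin_intended))
    write_num_csv(as.matrix(session$kin_intended),
                  file.path(path, "intended_kinematics.csv"),
                  names(session$kin_intended))
  meta <- c(list(format_version = SESSION_FORMAT_VERSION,
                 bin_size_ms = attr(session$sbp, "bin_size"),
                 mode = session$mode,
                 channel_mask = as.logical(attr(session$sbp, "channel_mask"))),
            session$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$format_version) ||
      meta$format_version != SESSION_FORMAT_VERSION)
    stop("unsupported session format version: ",
         if (is.null(meta$format_version)) "missing" else meta$format_version)
  sbp_raw <- read_num_csv(file.path(path, "sbp.csv"))
  kin_raw <- read_num_csv(file.path(path, "kinematics.csv"))
  tr_raw <- read_num_csv(file.path(path, "trials.csv"))
  kin <- as.data.frame(kin_raw$values)
  names(kin) <- kin_raw$header
  tr <- as.data.frame(tr_raw$values)
  names(tr) <- tr_raw$header
  tr$success <- tr$success > 0
  tr$excluded <- tr$excluded > 0
  for (nm in c("trial", "start_bin", "target_onset_bin", "acquire_bin",
               "end_bin"))
    tr[[nm]] <- as.integer(round(tr[[nm]]))
  kin$bin <- as.integer(round(kin$bin))
  ki <- NULL
  fki <- file.path(path, "intended_kinematics.csv")
  if (file.exists(fki)) {
    kr <- read_num_csv(fki)
    ki <- as.data.frame(kr$values)
    names(ki) <- kr$header
    ki$bin <- as.integer(round(ki$bin))
  }
  sbp <- sbp_matrix(t(sbp_raw$values), bin_size = meta$bin_size_ms,
                    channel_mask = meta$channel_mask)
  extra <- meta[setdiff(names(meta),
                        c("format_version", "bin_size_ms", "mode",
                          "channel_mask"))]
  session_bundle(sbp, kin, tr, mode = meta$mode, meta = extra,
                 kin_intended = ki)
}

#' Save / load a decoder model archive
#'
#' A directory of named flat numeric arrays (one CSV per array, 17
#' significant digits) plus a JSON manifest carrying the model kind, its
#' configuration, and a content checksum verified on load.
#'
#' @param model a `kalman_decoder`, `nn_decoder` or `steady_state_kalman`.
#' @param path directory to create/read.
#' @param expect_kind optional kind to require on load (`"kalman"`, `"nn"`,
#'   `"steady_state_kalman"`).
#' @return `save_model` returns `path` invisibly; `load_model` the decoder.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (inherits(model, "kalman_decoder")) {
    arrays <- model[c("A", "C", "W", "Q")]
    manifest <- list(kind = "kalman",
                     lag_bins = model$lag_bins,
                     n_feature_lags = model$n_feature_lags,
                     dt = model$dt, n_channels = model$n_channels,
                     position_uncertainty = model$position_uncertainty,
                     drop_position = model$drop_position,
                     channel_mask = model$channel_mask,
                     n_train_bins = model$n_train_bins)
  } else if (inherits(model, "nn_decoder")) {
    arrays <- c(model$params, model$running,
                list(target_mean = model$target_mean,
                     target_sd = model$target_sd,
                     gain = model$gain,
                     median_offset = model$median_offset))
    manifest <- list(kind = "nn", cfg = unclass(model$cfg),
                     seed = model$seed, trained = model$trained,
                     val_correlation = model$val_correlation,
                     param_names = names(model$params),
                     running_names = names(model$running),
                     array_dims = lapply(arrays, function(a)
                       if (is.matrix(a)) dim(a) else length(a)))
  } else if (inherits(model, "steady_state_kalman")) {
    arrays <- model[c("D", "K_v", "K_ss", "M", "G", "F_pos", "c_off",
                      "A", "C")]
    manifest <- list(kind = "steady_state_kalman",
                     alpha = model$alpha, beta = model$beta, dt = model$dt,
                     n_channels = model$n_channels,
                     n_feature_lags = model$n_feature_lags,
                     lag_bins = model$lag_bins)
  } else stop("unsupported model class")
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    m <- if (is.matrix(a)) a else matrix(a, nrow = 1)
    write_num_csv(m, file.path(path, paste0(nm, ".csv")),
                  paste0("c", seq_len(ncol(m))))
  }
  manifest$format_version <- MODEL_FORMAT_VERSION
  manifest$checksum <- content_checksum(arrays)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, expect_kind = NULL) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  if (is.null(man$format_version) ||
      man$format_version != MODEL_FORMAT_VERSION)
    stop("unsupported model format version")
  if (!is.null(expect_kind) && !identical(man$kind, expect_kind))
    stop("model kind mismatch: archive holds a '", man$kind,
         "' model, '", expect_kind, "' required")
  read_arr <- function(nm) read_num_csv(file.path(path, paste0(nm, ".csv")))$values
  if (man$kind == "kalman") {
    arrays <- lapply(c("A", "C", "W", "Q"), read_arr)
    names(arrays) <- c("A", "C", "W", "Q")
    model <- structure(c(arrays, list(
      lag_bins = as.integer(man$lag_bins),
      n_feature_lags = as.integer(man$n_feature_lags),
      dt = man$dt, n_channels = as.integer(man$n_channels),
      position_uncertainty = man$position_uncertainty,
      drop_position = man$drop_position,
      channel_mask = man$channel_mask,
      n_train_bins = man$n_train_bins)), class = "kalman_decoder")
    check <- arrays
  } else if (man$kind == "nn") {
    cfg <- structure(man$cfg, class = "nn_config")
    cfg$n_electrodes <- as.integer(cfg$n_electrodes)
    cfg$n_time_bins <- as.integer(cfg$n_time_bins)
    cfg$n_time_features <- as.integer(cfg$n_time_features)
    cfg$n_fc_layers <- as.integer(cfg$n_fc_layers)
    cfg$hidden <- as.integer(cfg$hidden)
    all_names <- c(man$param_names, man$running_names,
                   "target_mean", "target_sd", "gain", "median_offset")
    arrays <- list()
    for (nm in all_names) {
      m <- read_num_csv(file.path(path, paste0(nm, ".csv")))$values
      dims <- man$array_dims[[nm]]
      arrays[[nm]] <- if (length(dims) == 2) m else as.numeric(m)
    }
    model <- structure(list(
      cfg = cfg,
      params = arrays[man$param_names],
      running = if (length(man$running_names))
        arrays[man$running_names] else list(),
      target_mean = arrays$target_mean, target_sd = arrays$target_sd,
      gain = as.numeric(arrays$gain),
      median_offset = arrays$median_offset,
      trained = man$trained, seed = man$seed,
      val_correlation = man$val_correlation), class = "nn_decoder")
    check <- arrays
  } else if (man$kind == "steady_state_kalman") {
    nms <- c("D", "K_v", "K_ss", "M", "G", "F_pos", "c_off", "A", "C")
    arrays <- lapply(nms, read_arr)
    names(arrays) <- nms
    arrays$c_off <- as.numeric(arrays$c_off)
    model <- structure(c(arrays, list(
      alpha = man$alpha, beta = man$beta, dt = man$dt,
      n_channels = as.integer(man$n_channels),
      n_feature_lags = as.integer(man$n_feature_lags),
      lag_bins = as.integer(man$lag_bins))),
      class = "steady_state_kalman")
    check <- arrays
  } else stop("unknown model kind: ", man$kind)
  if (!identical(content_checksum(check), man$checksum))
    stop("integrity error: model archive checksum mismatch")
  model
}
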