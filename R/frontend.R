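#' Spike-band power from wideband recordings
#'
#' Replicates the real-time front end: each channel is band-pass filtered to
#' 300-1000 Hz (4th-order Butterworth applied forward and backward, so the
#' filter is zero-phase and introduces no lag), down-sampled to 2 kHz, full
#'-wave rectified (absolute value), and averaged in consecutive 50-ms bins.
#' A trailing partial bin is dropped, never padded.
#'
#' @param wideband channels x samples numeric matrix (a vector is treated as
#'   one channel).
#' @param fs sampling rate in Hz; must be at least 2000 and an integer
#'   multiple of 2000 so the down-sampling factor is exact.
#' @param band band edges in Hz (default `c(300, 1000)`).
#' @param order Butterworth order per pass (default 4).
#' @return an `sbp_matrix` with `floor(duration / 50 ms)` bins.
#' @export
#' @examples
#' x <- sin(2 * pi * 500 * seq(0, 1, by = 1 / 30000))
#' sbp <- compute_sbp_from_wideband(x, fs = 30000)
compute_sbp_from_wideband <- function(wideband, fs, band = c(300, 1000),
                                      order = 4) {
  if (is.null(dim(wideband))) wideband <- matrix(wideband, nrow = 1)
  if (fs < 2000) stop("fs must be at least 2000 Hz")
  dec <- fs / 2000
  if (abs(dec - round(dec)) > 1e-9)
    stop("fs must be an integer multiple of 2000 Hz")
  dec <- as.integer(round(dec))
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  bins_per <- as.integer(2000 * 0.05)  # samples per 50-ms bin at 2 kHz
  out <- t(apply(wideband, 1, function(x) {
    y <- filt_zero_phase(bf$b, bf$a, x)
    y <- y[seq(1, length(y), by = dec)]
    n_bins <- length(y) %/% bins_per
    if (n_bins < 1) stop("signal shorter than one 50-ms bin")
    y <- abs(y[seq_len(n_bins * bins_per)])
    colMeans(matrix(y, bins_per, n_bins))
  }))
  if (nrow(wideband) == 1) out <- matrix(out, nrow = 1)
  sbp_matrix(pmax(out, 0), bin_size = 50)
}

# Zero-phase filtering: odd-reflection padding at both ends (so start-up
# transients decay inside the padding, not the data), then a forward pass,
# reverse, forward pass, reverse. The padded difference-equation pipeline is
# simple enough for an independent loop implementation to reproduce it to
# machine precision.
filt_zero_phase <- function(b, a, x, pad_frac = 0.1) {
  n <- length(x)
  np <- min(n - 1L, max(as.integer(round(pad_frac * n)), 100L))
  head_pad <- 2 * x[1] - x[seq(np + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - np)]
  xx <- c(head_pad, x, tail_pad)
  y <- as.numeric(signal::filter(b, a, xx))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(np + 1L):(np + n)]
}
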