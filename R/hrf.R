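# Canonical hemodynamic response kernel used by the forward simulator.
# The analysis itself only uses window means, so kernel shape is a
# simulator convenience, not an analysis assumption.

#' Single-gamma hemodynamic response kernel
#'
#' @param t time in seconds (>= 0 contributes; t < 0 gives 0).
#' @param time_to_peak seconds to kernel maximum (default 7).
#' @param shape gamma shape parameter (default 8); scale is derived so
#'   the mode sits at `time_to_peak`.
#' @return kernel values, unit peak height.
#' @export
hrf_gamma <- function(t, time_to_peak = 7, shape = 8) {
  if (time_to_peak <= 0 || shape <= 1)
    abort_config("need time_to_peak > 0 and shape > 1")
  scale <- time_to_peak / (shape - 1)
  h <- ifelse(t < 0, 0, stats::dgamma(t, shape = shape, scale = scale))
  h / stats::dgamma(time_to_peak, shape = shape, scale = scale)
}

# Block regressor: boxcar convolved with the kernel, normalized so a
# single isolated block peaks at 1. Returns a length-n vector for the
# blocks of one condition.
block_regressor <- function(onsets_s, duration_s, n, fs,
                            time_to_peak = 7, shape = 8) {
  box <- numeric(n)
  for (o in onsets_s) {
    i0 <- floor(o * fs) + 1L
    i1 <- min(n, floor((o + duration_s) * fs))
    if (i0 <= n) box[i0:min(i1, n)] <- 1
  }
  tk <- seq(0, 40, by = 1 / fs)
  k <- hrf_gamma(tk, time_to_peak, shape)
  # peak of one isolated block response, for unit-amplitude scaling
  one <- stats::convolve(c(rep(1, round(duration_s * fs)),
                           numeric(length(tk))), rev(k), type = "open")
  r <- stats::convolve(box, rev(k), type = "open")[seq_len(n)]
  r / max(one)
}

# Mean of the single-block unit-peak response over the response window,
# used to convert designed window-mean amplitudes to kernel amplitudes.
block_window_mean <- function(duration_s, fs, window = c(0, 25),
                              time_to_peak = 7, shape = 8) {
  n <- ceiling((window[2] + 40) * fs)
  r <- block_regressor(0, duration_s, n, fs, time_to_peak, shape)
  idx <- seq(floor(window[1] * fs) + 1L, floor(window[2] * fs))
  mean(r[idx])
}
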