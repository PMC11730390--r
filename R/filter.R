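# Zero-phase band-pass filtering of optical density.

#' Zero-phase Butterworth band-pass for one series
#'
#' 3rd-order Butterworth applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift and doubled
#' attenuation.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi cut-off frequencies, Hz (default 0.01 and 0.50).
#' @param order filter order (default 3).
#' @return filtered vector.
#' @export
bp_filter <- function(x, fs, f_lo = 0.01, f_hi = 0.50, order = 3) {
  if (!(0 < f_lo && f_lo < f_hi && f_hi < fs / 2))
    abort_config("need 0 < f_lo < f_hi < fs/2")
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  n <- length(x)
  mu <- mean(x)
  # reflect-pad over the low-cut transient scale so start-up transients
  # of the recursion decay inside the padding, not the data
  np <- min(n - 1L, ceiling(2 / f_lo * fs))
  xp <- c(rev((x - mu)[seq_len(np) + 1L]), x - mu,
          rev((x - mu)[n - seq_len(np)]))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[np + seq_len(n)]
}

#' Band-pass filter an OD series
#'
#' Applies [bp_filter()] to every channel/wavelength. The pass band
#' (default 0.01--0.50 Hz) keeps the hemodynamic response while
#' removing slow drifts and cardiac pulsation.
#'
#' @param od an `od_series`.
#' @param f_lo,f_hi cut-offs in Hz.
#' @param order filter order.
#' @return filtered `od_series`.
#' @export
bandpass <- function(od, f_lo = 0.01, f_hi = 0.50, order = 3) {
  out <- od
  for (ch in seq_len(dim(od$dod)[2])) for (wl in seq_len(dim(od$dod)[3]))
    out$dod[, ch, wl] <- bp_filter(od$dod[, ch, wl], od$fs, f_lo, f_hi, order)
  out
}
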