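# Raw intensity -> optical density, and SNR-based channel pruning.

#' Convert raw intensities to optical-density changes
#'
#' Per channel and wavelength, \eqn{\Delta OD = -\log_{10}(I / \bar I)}
#' with \eqn{\bar I} the mean intensity over the whole recording.
#'
#' @param rec a `raw_recording` (see [simulate_subject()] or
#'   [read_recording_csv()]).
#' @return an `od_series`: list with `dod` (samples x channels x
#'   wavelengths), `fs`, `layout`, `channel_id`.
#' @export
intensity_to_od <- function(rec) {
  I <- rec$intensity
  if (any(!is.finite(I)) || any(I <= 0)) {
    bad <- which(apply(I <= 0 | !is.finite(I), 2, any))
    stop("nonpositive or non-finite intensity in channel(s) ",
         paste(rec$layout$channel_id[bad], collapse = ", "), call. = FALSE)
  }
  dod <- I
  for (w in seq_len(dim(I)[3]))
    dod[, , w] <- -log10(sweep(I[, , w, drop = FALSE][, , 1, drop = TRUE],
                               2, colMeans(I[, , w, drop = FALSE][, , 1, drop = TRUE]), "/"))
  structure(list(dod = dod, fs = rec$fs, layout = rec$layout,
                 channel_id = rec$layout$channel_id,
                 subject_id = rec$subject_id),
            class = "od_series")
}

#' Prune channels by raw-intensity signal-to-noise ratio
#'
#' A channel is retained iff `mean(I)/sd(I) >= snr_thresh` at every
#' wavelength. Channels with zero variance are treated as infinite SNR
#' and retained (logged via attribute `zero_variance`).
#'
#' @param rec a `raw_recording`.
#' @param snr_thresh SNR threshold (default 2, the discard rule `< 2`).
#' @return logical vector over channels (TRUE = keep), with attributes
#'   `snr` (channels x wavelengths matrix) and `zero_variance`.
#' @export
prune_channels <- function(rec, snr_thresh = 2) {
  I <- rec$intensity
  if (dim(I)[1] < 2) stop("need more than one sample for SNR", call. = FALSE)
  nch <- dim(I)[2]; nwl <- dim(I)[3]
  snr <- matrix(NA_real_, nch, nwl)
  zv <- matrix(FALSE, nch, nwl)
  for (w in seq_len(nwl)) {
    x <- I[, , w, drop = FALSE][, , 1, drop = TRUE]
    m <- colMeans(x); s <- apply(x, 2, stats::sd)
    zv[, w] <- s == 0
    snr[, w] <- ifelse(s == 0, Inf, m / s)
  }
  keep <- apply(snr >= snr_thresh, 1, all)
  attr(keep, "snr") <- snr
  attr(keep, "zero_variance") <- apply(zv, 1, any)
  keep
}

# subset an od_series to retained channels
od_subset <- function(od, keep) {
  structure(list(dod = od$dod[, keep, , drop = FALSE], fs = od$fs,
                 layout = od$layout,
                 channel_id = od$channel_id[keep],
                 subject_id = od$subject_id),
            class = "od_series")
}
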