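# Motion-artifact detection and spline correction on optical density.

# running max over trailing windows of w samples via shifted pmax
roll_extreme <- function(x, w, fun = pmax) {
  n <- length(x)
  out <- x
  if (w > 1) for (j in seq_len(w - 1L)) {
    shifted <- c(x[-seq_len(j)], rep(x[n], j))
    out <- fun(out, shifted)
  }
  out
}

#' Detect motion artifacts per channel
#'
#' A sample is flagged when, within any sliding window of `t_motion`
#' seconds covering it, the signal excursion (max minus min) exceeds
#' `std_thresh` times the channel's standard deviation or `amp_thresh`
#' in absolute OD units, at either wavelength. Flags are dilated by
#' `t_mask` seconds on each side. The channel sd is estimated robustly
#' from the sample-to-sample innovations (`mad(diff(x))/sqrt(2)`) so
#' that the artifacts being detected — including sustained baseline
#' shifts, which inflate any direct spread estimate — do not raise
#' their own detection threshold. Defaults
#' follow common practice for threshold-based fNIRS motion detection;
#' all are configurable.
#'
#' @param od an `od_series`.
#' @param t_motion sliding-window length, s (default 0.5).
#' @param t_mask dilation on each side of a flag, s (default 1.0).
#' @param std_thresh excursion threshold in channel-sd units (default 50).
#' @param amp_thresh absolute excursion threshold, OD (default 0.4).
#' @return an `artifact_mask`: logical matrix samples x channels
#'   (TRUE = motion-contaminated).
#' @export
detect_motion <- function(od, t_motion = 0.5, t_mask = 1.0,
                          std_thresh = 50, amp_thresh = 0.4) {
  if (any(c(t_motion, t_mask, std_thresh, amp_thresh) <= 0))
    abort_config("motion-detection parameters must be positive")
  n <- dim(od$dod)[1]; nch <- dim(od$dod)[2]; nwl <- dim(od$dod)[3]
  w <- max(2L, round(t_motion * od$fs))
  k <- round(t_mask * od$fs)
  mask <- matrix(FALSE, n, nch)
  for (ch in seq_len(nch)) {
    flag <- logical(n)
    for (wl in seq_len(nwl)) {
      x <- od$dod[, ch, wl]
      s <- stats::mad(diff(x)) / sqrt(2)  # robust innovation scale
      # windows starting at i cover samples i..i+w-1
      exc <- roll_extreme(x, w, pmax) - roll_extreme(x, w, pmin)
      hit <- if (s > 0) (exc > std_thresh * s) | (exc > amp_thresh)
      else exc > amp_thresh  # zero-variance channel: amplitude rule only
      starts <- which(hit[seq_len(n - w + 1L)])
      for (i in starts) flag[i:(i + w - 1L)] <- TRUE
    }
    if (k > 0 && any(flag)) {
      f <- as.numeric(flag)
      flag <- roll_extreme(f, k + 1L, pmax) > 0             # forward dilation
      flag <- rev(roll_extreme(rev(as.numeric(flag)), k + 1L, pmax) > 0)
    }
    mask[, ch] <- flag
  }
  class(mask) <- c("artifact_mask", class(mask))
  mask
}

#' Spline correction of flagged motion segments
#'
#' Within each flagged segment of at least `min_len` samples a cubic
#' smoothing spline (smoothness parameter `p`, 1 = interpolating) is
#' fitted; the segment is replaced by `v - s + line`, where `line`
#' interpolates the fit's boundary levels, so the artifact shape is
#' removed while the segment stays continuous with its neighbours.
#' The fit's level change across the segment, `s(end) - s(start)`,
#' estimates the artifact's persistent baseline shift: when its
#' magnitude exceeds `step_min` (a step-line artifact rather than a
#' spike), all subsequent samples are re-leveled by that constant.
#' Spike-like artifacts therefore leave samples outside their flagged
#' segment exactly unchanged, while step artifacts are corrected by a
#' single documented offset to everything after them. Flagged segments
#' too short for a spline fit are linearly interpolated across
#' (logged).
#'
#' @param od an `od_series`.
#' @param mask an `artifact_mask` aligned to `od`.
#' @param p smoothing parameter in (0, 1], mapped to
#'   `stats::smooth.spline(spar = 1 - p)` (default 0.99).
#' @param min_len minimum flagged-segment length for a spline fit
#'   (default 4 samples).
#' @param step_min minimum fitted level change (OD) treated as a
#'   baseline shift requiring re-leveling (default 0.05, well above
#'   the physiological OD noise floor).
#' @return corrected `od_series`.
#' @export
spline_correct <- function(od, mask, p = 0.99, min_len = 4L,
                           step_min = 0.05) {
  if (nrow(mask) != dim(od$dod)[1] || ncol(mask) != dim(od$dod)[2])
    stop("mask is not aligned to the OD series", call. = FALSE)
  if (p <= 0 || p > 1) abort_config("spline parameter p must be in (0, 1]")
  n <- dim(od$dod)[1]
  out <- od
  for (ch in seq_len(dim(od$dod)[2])) {
    m <- mask[, ch]
    if (!any(m)) next
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (wl in seq_len(dim(od$dod)[3])) {
      y <- od$dod[, ch, wl]
      for (si in which(r$values)) {
        idx <- starts[si]:ends[si]
        v <- y[idx]
        len <- length(v)
        if (len >= min_len) {
          fit <- stats::smooth.spline(seq_len(len), v, spar = 1 - p)
          s <- stats::predict(fit, seq_len(len))$y
          step <- s[len] - s[1]
          applied <- if (abs(step) > step_min) step else 0
          line <- seq(s[1], s[len] - applied, length.out = len)
          y[idx] <- v - s + line
          if (applied != 0 && ends[si] < n) {
            rest <- (ends[si] + 1L):n
            y[rest] <- y[rest] - applied
          }
        } else {
          # too short for a spline: bridge linearly between neighbours
          lo <- if (starts[si] > 1L) y[starts[si] - 1L] else v[1]
          hi <- if (ends[si] < n) y[ends[si] + 1L] else v[len]
          y[idx] <- seq(lo, hi, length.out = len + 2L)[2:(len + 1L)]
        }
      }
      out$dod[, ch, wl] <- y
    }
  }
  out
}
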