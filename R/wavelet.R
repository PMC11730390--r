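# Periodized multilevel discrete wavelet transform (Daubechies-2) and
# IQR-threshold wavelet motion correction.

db2_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))  # scaling (lowpass)
  g <- c(h[4], -h[3], h[2], -h[1])                         # wavelet (highpass)
  list(h = h, g = g)
}

# one analysis step on an even-length vector (periodic boundary)
dwt_step <- function(a) {
  f <- db2_filters()
  N <- length(a)
  k <- seq.int(0L, N / 2L - 1L)
  lo <- hi <- numeric(N / 2L)
  for (m in 0:3) {
    idx <- ((2L * k + m) %% N) + 1L
    lo <- lo + f$h[m + 1L] * a[idx]
    hi <- hi + f$g[m + 1L] * a[idx]
  }
  list(a = lo, d = hi)
}

idwt_step <- function(lo, hi) {
  f <- db2_filters()
  N <- 2L * length(lo)
  k <- seq.int(0L, N / 2L - 1L)
  x <- numeric(N)
  for (m in 0:3) {
    idx <- ((2L * k + m) %% N) + 1L
    x[idx] <- x[idx] + f$h[m + 1L] * lo + f$g[m + 1L] * hi
  }
  x
}

#' Multilevel periodized db2 wavelet decomposition
#'
#' @param x numeric vector; length must be a power of two.
#' @param levels decomposition depth; default the maximum leaving at
#'   least 4 approximation coefficients.
#' @return list with `approx` (coarsest approximation) and `details`
#'   (list of detail coefficient vectors, finest first).
#' @export
dwt_db2 <- function(x, levels = NULL) {
  N <- length(x)
  if (N < 8 || bitwAnd(N, N - 1L) != 0)
    stop("dwt_db2 needs a power-of-two length >= 8", call. = FALSE)
  maxlev <- floor(log2(N / 4))
  if (is.null(levels)) levels <- maxlev
  levels <- min(levels, maxlev)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

#' Inverse of [dwt_db2()]
#' @param w a decomposition from [dwt_db2()].
#' @return reconstructed vector.
#' @export
idwt_db2 <- function(w) {
  a <- w$approx
  for (j in rev(seq_along(w$details))) a <- idwt_step(a, w$details[[j]])
  a
}

# symmetric (reflecting) pad to the next power of two
pad_pow2 <- function(x) {
  n <- length(x)
  N <- 2^ceiling(log2(max(n, 8)))
  if (N == n) return(list(x = x, n = n))
  ext <- N - n
  refl <- rev(x)[seq_len(min(ext, n))]
  while (length(refl) < ext) refl <- c(refl, rev(refl))[seq_len(ext)]
  list(x = c(x, refl[seq_len(ext)]), n = n)
}

#' Wavelet motion correction by interquartile thresholding
#'
#' Per channel and wavelength the OD series is decomposed with a
#' periodized multilevel db2 transform (after symmetric padding to a
#' power of two). At each thresholded detail level, coefficients
#' outside `[Q1 - alpha*IQR, Q3 + alpha*IQR]` are set to zero — large
#' coefficients are the signature of abrupt motion transients — and
#' the series is reconstructed. `alpha = Inf` disables zeroing and
#' returns the input (perfect reconstruction).
#'
#' Thresholding is restricted to detail levels whose frequency band
#' lies entirely above `f_protect`: motion transients (spikes, jump
#' edges) are broadband and dominated by fast scales, while the
#' block-design hemodynamic response is confined below ~0.05 Hz, where
#' coefficient zeroing would attenuate the response itself rather than
#' artifacts. `f_protect = 0` thresholds every level.
#'
#' @param od an `od_series`.
#' @param alpha interquartile multiplier (default 0.50).
#' @param f_protect lower edge (Hz) of the protected hemodynamic band
#'   (default 0.06).
#' @return corrected `od_series`.
#' @export
wavelet_correct <- function(od, alpha = 0.50, f_protect = 0.06) {
  if (!is_scalar_num(alpha) && !identical(alpha, Inf))
    abort_config("alpha must be a positive scalar (Inf disables zeroing)")
  if (alpha <= 0) abort_config("alpha must be > 0")
  out <- od
  for (ch in seq_len(dim(od$dod)[2])) for (wl in seq_len(dim(od$dod)[3])) {
    x <- od$dod[, ch, wl]
    pad <- pad_pow2(x)
    w <- dwt_db2(pad$x)
    if (is.finite(alpha)) {
      for (j in seq_along(w$details)) {
        if (od$fs / 2^(j + 1) < f_protect) next  # level overlaps response band
        d <- w$details[[j]]
        q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
        iqr <- q[2] - q[1]
        d[d < q[1] - alpha * iqr | d > q[2] + alpha * iqr] <- 0
        w$details[[j]] <- d
      }
    }
    out$dod[, ch, wl] <- idwt_db2(w)[seq_len(pad$n)]
  }
  out
}
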