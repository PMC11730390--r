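# Block epoching, baseline correction, trial rejection, averaging,
# and subject-inclusion bookkeeping.

#' Epoch a concentration series around block onsets and average
#'
#' For every block, the window `window` (default \[-2, 25) s, half-open
#' at the right) is extracted from the continuous series and the mean
#' of the `baseline` window (default \[-5, 0) s) is subtracted per
#' channel. A trial is rejected outright when more than
#' `max_flag_frac` of its (epoch + baseline) samples are flagged on
#' average across channels; in addition, individual channels whose own
#' flagged fraction exceeds the tolerance are dropped from that
#' trial's average only, since motion contamination is channel-local.
#' Retained trials are averaged per condition and channel.
#'
#' @param conc a `conc_series` (see [od_to_conc()]).
#' @param schedule a `stim_schedule`.
#' @param mask optional `artifact_mask` (samples x channels) of
#'   residual flags, aligned to `conc`; columns must correspond to the
#'   channels present in `conc`.
#' @param window epoch window in seconds relative to onset, half-open.
#' @param baseline baseline window in seconds, half-open.
#' @param max_flag_frac trial-rejection tolerance (default 0.1).
#' @return an `epoch_average`: list with per-condition `hbo`/`hbr`
#'   matrices (window samples x channels), `time_s`, `n_trials`,
#'   `n_total` per condition, `channel_id`, `rejected` (per-block
#'   logical), and `notes` recording conditions with zero retained
#'   trials.
#' @export
epoch_and_average <- function(conc, schedule, mask = NULL,
                              window = c(-2, 25), baseline = c(-5, 0),
                              max_flag_frac = 0.1) {
  fs <- conc$fs
  n <- nrow(conc$hbo)
  off_win <- seq.int(floor(window[1] * fs), ceiling(window[2] * fs) - 1L)
  off_bl  <- seq.int(floor(baseline[1] * fs), ceiling(baseline[2] * fs) - 1L)
  onset_i <- round(schedule$onset_s * fs) + 1L
  lo <- min(off_win[1], off_bl[1]); hi <- max(off_win[length(off_win)], 0L)
  if (any(onset_i + lo < 1L) || any(onset_i + hi > n))
    stop("epoch/baseline window falls outside the recording", call. = FALSE)
  if (!is.null(mask) && (nrow(mask) != n || ncol(mask) != ncol(conc$hbo)))
    stop("mask is not aligned to the concentration series", call. = FALSE)

  nb <- nrow(schedule)
  nch <- ncol(conc$hbo)
  rejected <- logical(nb)
  ch_keep <- matrix(TRUE, nb, nch)   # channel-trial retention
  epochs_hbo <- epochs_hbr <- vector("list", nb)
  for (b in seq_len(nb)) {
    rows <- onset_i[b] + off_win
    bl_rows <- onset_i[b] + off_bl
    if (!is.null(mask)) {
      all_rows <- unique(c(bl_rows, rows))
      frac_ch <- colMeans(mask[all_rows, , drop = FALSE])
      if (mean(frac_ch) > max_flag_frac) { rejected[b] <- TRUE; next }
      ch_keep[b, ] <- frac_ch <= max_flag_frac
    }
    bl_o <- colMeans(conc$hbo[bl_rows, , drop = FALSE])
    bl_r <- colMeans(conc$hbr[bl_rows, , drop = FALSE])
    epochs_hbo[[b]] <- sweep(conc$hbo[rows, , drop = FALSE], 2, bl_o)
    epochs_hbr[[b]] <- sweep(conc$hbr[rows, , drop = FALSE], 2, bl_r)
  }

  conditions <- levels(schedule$condition)
  avg <- list(); n_trials <- n_total <- stats::setNames(integer(length(conditions)), conditions)
  notes <- character()
  for (cond in conditions) {
    sel <- which(schedule$condition == cond & !rejected)
    n_total[cond] <- sum(schedule$condition == cond)
    n_trials[cond] <- length(sel)
    if (!length(sel)) {
      notes <- c(notes, sprintf("condition '%s': zero retained trials", cond))
      avg[[cond]] <- NULL
      next
    }
    sum_o <- sum_r <- matrix(0, length(off_win), nch)
    cnt <- matrix(0, 1, nch)
    for (b in sel) {
      keep <- ch_keep[b, ]
      if (!any(keep)) next
      sum_o[, keep] <- sum_o[, keep] + epochs_hbo[[b]][, keep, drop = FALSE]
      sum_r[, keep] <- sum_r[, keep] + epochs_hbr[[b]][, keep, drop = FALSE]
      cnt[, keep] <- cnt[, keep] + 1
    }
    if (all(cnt == 0)) {
      notes <- c(notes, sprintf("condition '%s': zero retained trials", cond))
      avg[[cond]] <- NULL
      next
    }
    cnt_safe <- pmax(cnt, 1)
    avg[[cond]] <- list(
      hbo = sweep(sum_o, 2, cnt_safe, "/"),
      hbr = sweep(sum_r, 2, cnt_safe, "/"),
      n_channel_trials = as.integer(cnt)
    )
  }
  structure(list(conditions = avg, time_s = off_win / fs,
                 n_trials = n_trials, n_total = n_total,
                 channel_id = conc$channel_id, layout = conc$layout,
                 fs = fs, rejected = rejected, channel_trials = ch_keep,
                 notes = notes),
            class = "epoch_average")
}

#' Subject inclusion decision
#'
#' A subject is included iff at least `min_channels` channels survived
#' pruning and at least a fraction `min_trial_frac` of trials was
#' retained; both boundaries count as included ("at least").
#'
#' @param channel_keep logical channel-retention vector (from
#'   [prune_channels()]).
#' @param n_retained,n_total retained/total trial counts (scalars or
#'   per-condition vectors, summed).
#' @param min_channels minimum retained channels (default 18).
#' @param min_trial_frac minimum retained-trial fraction (default 0.5).
#' @return list: `retained_channels`, `retained_trial_fraction`,
#'   `included`, `reasons` (character, empty when included).
#' @export
assess_inclusion <- function(channel_keep, n_retained, n_total,
                             min_channels = 18, min_trial_frac = 0.5) {
  rc <- sum(channel_keep)
  tf <- sum(n_retained) / sum(n_total)
  reasons <- character()
  if (rc < min_channels)
    reasons <- c(reasons, sprintf("only %d channels retained (< %d)", rc, min_channels))
  if (tf < min_trial_frac)
    reasons <- c(reasons, sprintf("only %.0f%% of trials retained (< %.0f%%)",
                                  100 * tf, 100 * min_trial_frac))
  list(retained_channels = rc, retained_trial_fraction = tf,
       included = length(reasons) == 0L, reasons = reasons)
}
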