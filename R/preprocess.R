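# The full preprocessing chain, in the fixed order:
# OD -> SNR prune -> motion detect -> spline -> wavelet -> band-pass
# -> modified Beer-Lambert -> epoch/average.

#' Preprocessing configuration
#'
#' All tunables of the preprocessing chain with their defaults:
#' SNR pruning threshold 2; motion detection window 0.5 s, mask
#' dilation 1 s, excursion thresholds 50 sd / 0.4 OD; spline parameter
#' 0.99; wavelet alpha 0.50; 3rd-order zero-phase Butterworth band-pass
#' 0.01--0.50 Hz; neonatal age 0 for the DPF; epoch window \[-2, 25) s
#' with baseline \[-5, 0) s; trials rejected above 10% residual
#' flagging; inclusion at >= 18 channels and >= 50% trials.
#' `motion_correct` and `filter_on` switch those stages off for
#' round-trip diagnostics.
#'
#' @param snr_thresh,t_motion,t_mask,std_thresh,amp_thresh,spline_p,wavelet_alpha,f_lo,f_hi,filter_order,age,window,baseline,max_flag_frac,min_channels,min_trial_frac stage parameters (see stage functions).
#' @param motion_correct,filter_on logical stage switches.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(snr_thresh = 2,
                              t_motion = 0.5, t_mask = 1.0,
                              std_thresh = 50, amp_thresh = 0.4,
                              spline_p = 0.99, spline_step_min = 0.05,
                              wavelet_alpha = 0.50,
                              wavelet_f_protect = 0.06,
                              f_lo = 0.01, f_hi = 0.50, filter_order = 3,
                              age = 0,
                              window = c(-2, 25), baseline = c(-5, 0),
                              max_flag_frac = 0.1,
                              min_channels = 18, min_trial_frac = 0.5,
                              motion_correct = TRUE, filter_on = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "preprocess_config"
  cfg
}

#' Run the preprocessing chain on one recording
#'
#' @param rec a `raw_recording`.
#' @param schedule the subject's `stim_schedule` (defaults to the one
#'   attached by the simulator, if present).
#' @param config a [preprocess_config()].
#' @param extinction optional extinction-matrix override.
#' @return list: `epochs` (an `epoch_average`), `conc` (`conc_series`
#'   restricted to retained channels), `channel_keep`, `mask`,
#'   `inclusion` (see [assess_inclusion()]), and `log` (character
#'   vector, one line per stage/decision).
#' @export
preprocess_recording <- function(rec, schedule = attr(rec, "schedule"),
                                 config = preprocess_config(),
                                 extinction = NULL) {
  if (is.null(schedule))
    stop("no stimulus schedule supplied for ", rec$subject_id, call. = FALSE)
  log <- sprintf("[%s] chain: OD -> prune -> detect -> spline -> wavelet -> band-pass -> Beer-Lambert -> epoch",
                 rec$subject_id)

  keep <- prune_channels(rec, config$snr_thresh)
  if (any(attr(keep, "zero_variance")))
    log <- c(log, sprintf("zero-variance channel(s) %s retained by SNR rule",
                          paste(rec$layout$channel_id[attr(keep, "zero_variance")],
                                collapse = ",")))
  log <- c(log, sprintf("pruned %d/%d channels (SNR < %g)",
                        sum(!keep), length(keep), config$snr_thresh))

  od <- intensity_to_od(rec)
  od <- od_subset(od, keep)

  if (config$motion_correct && sum(keep) > 0) {
    mask <- detect_motion(od, config$t_motion, config$t_mask,
                          config$std_thresh, config$amp_thresh)
    log <- c(log, sprintf("motion: %.2f%% samples flagged", 100 * mean(mask)))
    od <- spline_correct(od, mask, config$spline_p,
                         step_min = config$spline_step_min)
    od <- wavelet_correct(od, config$wavelet_alpha, config$wavelet_f_protect)
  } else {
    mask <- matrix(FALSE, dim(od$dod)[1], dim(od$dod)[2])
    log <- c(log, "motion correction disabled")
  }
  if (config$filter_on) {
    od <- bandpass(od, config$f_lo, config$f_hi, config$filter_order)
  } else log <- c(log, "band-pass disabled")

  conc <- od_to_conc(od, rec$layout, config$age, extinction)
  ep <- epoch_and_average(conc, schedule, mask,
                          config$window, config$baseline, config$max_flag_frac)
  if (length(ep$notes)) log <- c(log, paste0("averaging: ", ep$notes))
  log <- c(log, sprintf("trials retained: %d/%d", sum(ep$n_trials), sum(ep$n_total)))

  incl <- assess_inclusion(keep, ep$n_trials, ep$n_total,
                           config$min_channels, config$min_trial_frac)
  if (length(ep$notes)) {
    incl$included <- FALSE
    incl$reasons <- c(incl$reasons, ep$notes)
  }
  if (!incl$included)
    log <- c(log, paste0("EXCLUDED: ", paste(incl$reasons, collapse = "; ")))

  list(subject_id = rec$subject_id, epochs = ep, conc = conc,
       channel_keep = keep, mask = mask, inclusion = incl, log = log)
}
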