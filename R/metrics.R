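# Per-subject speech-discrimination metrics: SP, SP_L, SP_R, the
# laterality index, response-sign classification, and signed variants.

#' Per-channel condition means of the averaged response
#'
#' Time-mean of the baseline-corrected HbO (or HbR) epoch average over
#' the response window, per channel and condition.
#'
#' @param ep an `epoch_average`.
#' @param channels channel ids to include (default: all present).
#' @param response_window window in seconds post onset (default
#'   `c(0, 25)`, the full post-stimulus epoch).
#' @param chromophore `"hbo"` (default) or `"hbr"`.
#' @return matrix channels x conditions of window means (uM); rownames
#'   are channel ids.
#' @export
condition_mean <- function(ep, channels = ep$channel_id,
                           response_window = c(0, 25),
                           chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  sel <- match(channels, ep$channel_id)
  if (!length(sel) || anyNA(sel))
    stop("empty or unknown channel subset", call. = FALSE)
  rows <- ep$time_s >= response_window[1] & ep$time_s < response_window[2]
  conds <- names(ep$conditions)
  out <- matrix(NA_real_, length(sel), length(conds),
                dimnames = list(channels, conds))
  for (cond in conds) {
    if (is.null(ep$conditions[[cond]])) next
    m <- ep$conditions[[cond]][[chromophore]]
    out[, cond] <- colMeans(m[rows, sel, drop = FALSE])
  }
  out
}

# channel-mean of forward-minus-reverse window means over a channel set
fr_difference <- function(cm, channels, ids) {
  sel <- ids %in% channels
  if (!any(sel)) return(NA_real_)
  mean(cm[sel, "forward"] - cm[sel, "reverse"])
}

#' Speech-discrimination metrics SP, SP_L, SP_R
#'
#' SP is the absolute difference in mean HbO changes between the
#' forward and reverse condition over all retained channels; SP_L and
#' SP_R restrict to the left/right hemisphere. The per-channel
#' forward-minus-reverse differences are averaged across channels
#' first, then the absolute value is taken (`aggregation =
#' "mean_first"`); `"abs_first"` (mean of per-channel absolute
#' differences) is available for sensitivity analysis.
#'
#' @param ep an `epoch_average`.
#' @param layout the `probe_layout` (default from `ep`).
#' @param response_window seconds post onset (default `c(0, 25)`).
#' @param aggregation `"mean_first"` (default) or `"abs_first"`.
#' @return list `sp`, `sp_l`, `sp_r` (uM, >= 0; `NA` for a hemisphere
#'   with no retained channels).
#' @export
speech_discrimination <- function(ep, layout = ep$layout,
                                  response_window = c(0, 25),
                                  aggregation = c("mean_first", "abs_first")) {
  aggregation <- match.arg(aggregation)
  s <- signed_discrimination(ep, layout, response_window, aggregation)
  list(sp = abs(s$signed_sp), sp_l = abs(s$signed_sp_l),
       sp_r = abs(s$signed_sp_r))
}

#' Signed (algebraic) discrimination metrics
#'
#' Identical aggregation to [speech_discrimination()] without the
#' absolute value; intended for analyses run separately within the
#' positive- and inverted-response groups, where algebraic values do
#' not cancel.
#'
#' @inheritParams speech_discrimination
#' @return list `signed_sp`, `signed_sp_l`, `signed_sp_r` (uM).
#' @export
signed_discrimination <- function(ep, layout = ep$layout,
                                  response_window = c(0, 25),
                                  aggregation = c("mean_first", "abs_first")) {
  aggregation <- match.arg(aggregation)
  if (any(vapply(c("forward", "reverse"),
                 function(cc) is.null(ep$conditions[[cc]]), logical(1))))
    stop("both condition averages must be present", call. = FALSE)
  cm <- condition_mean(ep, response_window = response_window)
  diffs <- cm[, "forward"] - cm[, "reverse"]
  if (aggregation == "abs_first") diffs <- abs(diffs)
  agg <- function(hemi) {
    ids <- if (is.null(hemi)) ep$channel_id else channels_of(layout, hemi)
    sel <- ep$channel_id %in% ids
    if (!any(sel)) return(NA_real_)
    mean(diffs[sel])
  }
  list(signed_sp = agg(NULL), signed_sp_l = agg("L"), signed_sp_r = agg("R"))
}

#' Hemispheric laterality index
#'
#' \deqn{LI = \frac{SP_L - SP_R}{SP_L + SP_R} \times 100}
#' +100 is complete left-hemisphere dominance, -100 complete right
#' dominance. Undefined (returns `NA` with attribute
#' `undefined = TRUE`) when both metrics are zero; such subjects are
#' excluded from laterality analyses.
#'
#' @param sp_l,sp_r non-negative hemispheric discrimination metrics.
#' @return LI in \[-100, 100\], or flagged `NA`.
#' @export
laterality_index <- function(sp_l, sp_r) {
  if (is.na(sp_l) || is.na(sp_r)) return(NA_real_)
  if (sp_l < 0 || sp_r < 0)
    stop("sp_l and sp_r must be >= 0 (absolute metrics)", call. = FALSE)
  if (sp_l + sp_r == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (sp_l - sp_r) / (sp_l + sp_r) * 100
}

#' Classify the direction of the HbO response
#'
#' A subject is classified `"inv"` (inverted responder) iff the
#' all-channel mean HbO change over the response window in the forward
#' condition is negative; an exactly zero mean is classified `"pos"`
#' with attribute `ambiguous = TRUE`.
#'
#' @param ep an `epoch_average`.
#' @param response_window seconds post onset.
#' @return `"pos"` or `"inv"`.
#' @export
response_sign <- function(ep, response_window = c(0, 25)) {
  if (is.null(ep$conditions[["forward"]]))
    stop("forward-condition average missing", call. = FALSE)
  cm <- condition_mean(ep, response_window = response_window)
  m <- mean(cm[, "forward"])
  out <- if (m < 0) "inv" else "pos"
  if (m == 0) attr(out, "ambiguous") <- TRUE
  out
}

#' Full metrics row for one preprocessed subject
#'
#' @param pp result of [preprocess_recording()].
#' @param response_window,aggregation forwarded to the metric functions.
#' @return one-row data frame: `subject_id`, `included`, `sp`, `sp_l`,
#'   `sp_r`, `li_sp`, `sign`, `signed_sp`, `signed_sp_l`,
#'   `signed_sp_r`, `retained_channels`, `retained_trial_fraction`.
#' @export
subject_metrics <- function(pp, response_window = c(0, 25),
                            aggregation = "mean_first") {
  ep <- pp$epochs
  id <- pp$subject_id %||% NA_character_
  if (!pp$inclusion$included || length(ep$notes)) {
    return(data.frame(subject_id = id, included = FALSE,
                      sp = NA_real_, sp_l = NA_real_, sp_r = NA_real_,
                      li_sp = NA_real_, sign = NA_character_,
                      signed_sp = NA_real_, signed_sp_l = NA_real_,
                      signed_sp_r = NA_real_,
                      retained_channels = pp$inclusion$retained_channels,
                      retained_trial_fraction = pp$inclusion$retained_trial_fraction,
                      stringsAsFactors = FALSE))
  }
  sd_ <- speech_discrimination(ep, response_window = response_window,
                               aggregation = aggregation)
  sg <- signed_discrimination(ep, response_window = response_window,
                              aggregation = aggregation)
  li <- if (is.na(sd_$sp_l) || is.na(sd_$sp_r)) NA_real_ else
    as.numeric(laterality_index(sd_$sp_l, sd_$sp_r))
  data.frame(
    subject_id = id,
    included = pp$inclusion$included,
    sp = sd_$sp, sp_l = sd_$sp_l, sp_r = sd_$sp_r, li_sp = li,
    sign = as.character(response_sign(ep, response_window)),
    signed_sp = sg$signed_sp, signed_sp_l = sg$signed_sp_l,
    signed_sp_r = sg$signed_sp_r,
    retained_channels = pp$inclusion$retained_channels,
    retained_trial_fraction = pp$inclusion$retained_trial_fraction,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
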