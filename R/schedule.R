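#' Generate a pseudo-randomized block-design stimulus schedule
#'
#' Builds an alternating forward/reverse speech block schedule:
#' `n_per_condition` blocks of each condition, each of `block_dur`
#' seconds, separated by silences of random length drawn uniformly from
#' `isi_range`, with no more than `max_run` consecutive blocks of the
#' same condition. This mirrors the neonatal paradigm of 10 forward and
#' 10 reverse 15-s speech sequences separated by 15--30 s silences.
#'
#' @param n_per_condition number of blocks per condition (default 10).
#' @param block_dur block duration in seconds (default 15).
#' @param isi_range length-2 numeric, min/max inter-stimulus silence in
#'   seconds (default `c(15, 30)`).
#' @param max_run maximum number of consecutive same-condition blocks
#'   (default 2).
#' @param seed integer seed; identical seeds give identical schedules.
#' @param lead_in_s silence before the first block onset, seconds. Must
#'   leave room for the pre-stimulus baseline window (default 10).
#' @return an object of class `stim_schedule`: a data frame with
#'   columns `onset_s`, `duration_s`, `condition` (factor
#'   forward/reverse), ordered by strictly increasing onset.
#' @examples
#' sch <- make_schedule(seed = 1)
#' table(sch$condition)
#' @export
make_schedule <- function(n_per_condition = 10, block_dur = 15,
                          isi_range = c(15, 30), max_run = 2, seed = 1,
                          lead_in_s = 10) {
  if (!is_count(n_per_condition) || n_per_condition < 1)
    abort_config("`n_per_condition` must be >= 1")
  if (!is_scalar_num(block_dur) || block_dur <= 0)
    abort_config("`block_dur` must be > 0")
  if (length(isi_range) != 2 || isi_range[1] > isi_range[2] || isi_range[1] < 0)
    abort_config("`isi_range` must be (min, max) with 0 <= min <= max")
  if (!is_count(max_run) || max_run < 1)
    abort_config("`max_run` must be >= 1")

  conditions <- c("forward", "reverse")
  order <- with_seed(seed, {
    rem <- c(forward = n_per_condition, reverse = n_per_condition)
    run_cond <- NA_character_
    run_len <- 0L
    out <- character(2L * n_per_condition)
    for (i in seq_along(out)) {
      ok <- vapply(conditions, function(cc) {
        if (rem[[cc]] == 0L) return(FALSE)
        r_new <- if (identical(cc, run_cond)) run_len + 1L else 1L
        if (r_new > max_run) return(FALSE)
        s <- rem[[cc]] - 1L
        o <- rem[[setdiff(conditions, cc)]]
        # remaining same-condition blocks must fit around the others
        s <= (max_run - r_new) + o * max_run && o <= (s + 1L) * max_run
      }, logical(1))
      if (!any(ok))
        abort_config("infeasible schedule constraints: n_per_condition = ",
                     n_per_condition, ", max_run = ", max_run)
      pick <- if (sum(ok) == 1L) conditions[ok] else sample(conditions[ok], 1L)
      out[i] <- pick
      rem[[pick]] <- rem[[pick]] - 1L
      run_len <- if (identical(pick, run_cond)) run_len + 1L else 1L
      run_cond <- pick
    }
    gaps <- stats::runif(length(out) - 1L, isi_range[1], isi_range[2])
    list(cond = out, gaps = gaps)
  })

  onsets <- lead_in_s + c(0, cumsum(order$gaps + block_dur))
  sch <- data.frame(
    onset_s    = onsets,
    duration_s = block_dur,
    condition  = factor(order$cond, levels = conditions),
    stringsAsFactors = FALSE
  )
  class(sch) <- c("stim_schedule", "data.frame")
  validate_schedule(sch, isi_range = isi_range, max_run = max_run)
  sch
}

#' Validate a stimulus schedule
#'
#' Checks the structural invariants of a block schedule: strictly
#' increasing onsets, non-negative gaps (optionally within ISI bounds),
#' and the maximum same-condition run length.
#'
#' @param sch a `stim_schedule` or data frame with `onset_s`,
#'   `duration_s`, `condition`.
#' @param isi_range optional ISI bounds to enforce on inter-block gaps.
#' @param max_run optional maximum run length to enforce.
#' @return `sch`, invisibly; errors describe the violated invariant.
#' @export
validate_schedule <- function(sch, isi_range = NULL, max_run = NULL) {
  need <- c("onset_s", "duration_s", "condition")
  if (!all(need %in% names(sch)))
    stop("schedule must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(sch) == 0) stop("schedule has no blocks", call. = FALSE)
  if (is.unsorted(sch$onset_s, strictly = TRUE))
    stop("schedule onsets must be strictly increasing", call. = FALSE)
  gaps <- utils::head(sch$onset_s[-1] - (sch$onset_s + sch$duration_s)[-nrow(sch)], -0)
  if (nrow(sch) > 1 && any(gaps < -1e-9))
    stop("schedule blocks overlap", call. = FALSE)
  if (!is.null(isi_range) && nrow(sch) > 1 &&
      (any(gaps < isi_range[1] - 1e-9) || any(gaps > isi_range[2] + 1e-9)))
    stop("inter-block gap outside ISI bounds", call. = FALSE)
  if (!is.null(max_run)) {
    runs <- rle(as.character(sch$condition))$lengths
    if (max(runs) > max_run)
      stop("same-condition run exceeds max_run", call. = FALSE)
  }
  invisible(sch)
}

schedule_end_s <- function(sch) max(sch$onset_s + sch$duration_s)
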