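#' Construct an fNIRS probe layout
#'
#' A probe layout describes the measurement channels of a bilateral
#' optode array: channel ids, the source/detector pair behind each
#' channel, the hemisphere the channel samples, the source--detector
#' separation and the two laser wavelengths.
#'
#' @param n_channels total number of channels; must be even so that the
#'   two hemispheres carry the same number (default 24, i.e. 12 per
#'   hemisphere, as in a neonatal bilateral temporal array).
#' @param distance_cm source--detector separation in centimetres.
#'   Defaults to 3 cm, a typical neonatal channel separation. Distance
#'   rescales recovered concentrations linearly and cancels in the
#'   laterality index.
#' @param wavelengths two distinct laser wavelengths in nanometres
#'   (default `c(695, 830)`).
#' @return an object of class `probe_layout`: a data frame with columns
#'   `channel_id`, `source_id`, `detector_id`, `hemisphere` (`"L"`/`"R"`),
#'   `distance_cm`, plus a `wavelengths` attribute.
#' @examples
#' layout <- probe_layout()
#' table(layout$hemisphere)
#' @export
probe_layout <- function(n_channels = 24, distance_cm = 3.0,
                         wavelengths = c(695, 830)) {
  if (!is_count(n_channels) || n_channels < 2 || n_channels %% 2 != 0)
    abort_config("`n_channels` must be an even count >= 2")
  if (!is_scalar_num(distance_cm) || distance_cm <= 0)
    abort_config("`distance_cm` must be > 0")
  if (length(wavelengths) != 2 || anyDuplicated(wavelengths))
    abort_config("`wavelengths` must be two distinct values (nm)")
  half <- n_channels / 2
  layout <- data.frame(
    channel_id  = seq_len(n_channels),
    source_id   = rep(seq_len(half), 2L),
    detector_id = rep(seq_len(half), 2L),
    hemisphere  = rep(c("L", "R"), each = half),
    distance_cm = distance_cm,
    stringsAsFactors = FALSE
  )
  attr(layout, "wavelengths") <- as.numeric(wavelengths)
  class(layout) <- c("probe_layout", "data.frame")
  layout
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout> %d channels (%d L / %d R), d = %g cm, wavelengths %s nm\n",
              nrow(x), sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              x$distance_cm[1], paste(attr(x, "wavelengths"), collapse = "/")))
  invisible(x)
}

layout_wavelengths <- function(layout) attr(layout, "wavelengths")

channels_of <- function(layout, hemisphere = NULL) {
  if (is.null(hemisphere)) return(layout$channel_id)
  layout$channel_id[layout$hemisphere == hemisphere]
}
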