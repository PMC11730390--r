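# Interchange formats: plain CSV dialects (always available) and SNIRF
# (HDF5, via the optional rhdf5 backend). All dialects are UTF-8,
# comma-separated, header row, "." decimal.

#' Write / read a raw recording as long-format CSV
#'
#' Columns: `channel_id`, `wavelength_nm`, `time_s`, `intensity`.
#'
#' @param rec a `raw_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  wl <- layout_wavelengths(rec$layout)
  n <- dim(rec$intensity)[1]; nch <- dim(rec$intensity)[2]
  tt <- (seq_len(n) - 1) / rec$fs
  df <- data.frame(
    channel_id = rep(rec$layout$channel_id, each = n, times = 2L),
    wavelength_nm = rep(wl, each = n * nch),
    time_s = rep(tt, nch * 2L),
    intensity = c(rec$intensity[, , 1L], rec$intensity[, , 2L])
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param layout probe layout to attach (channel set must match).
#' @param subject_id identifier for the reconstructed recording.
#' @export
read_recording_csv <- function(path, layout = probe_layout(),
                               subject_id = basename(path)) {
  df <- utils::read.csv(path)
  need <- c("channel_id", "wavelength_nm", "time_s", "intensity")
  if (!all(need %in% names(df)))
    stop("malformed recording CSV ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  wl <- sort(unique(df$wavelength_nm))
  chs <- sort(unique(df$channel_id))
  if (!identical(as.numeric(wl), as.numeric(layout_wavelengths(layout))))
    stop("wavelengths in ", path, " do not match layout", call. = FALSE)
  tt <- sort(unique(df$time_s))
  fs <- 1 / stats::median(diff(tt))
  arr <- array(NA_real_, c(length(tt), length(chs), length(wl)))
  for (w in seq_along(wl)) for (ci in seq_along(chs)) {
    sub <- df[df$wavelength_nm == wl[w] & df$channel_id == chs[ci], ]
    arr[, ci, w] <- sub$intensity[order(sub$time_s)]
  }
  if (anyNA(arr)) stop("incomplete recording CSV ", path, call. = FALSE)
  structure(list(intensity = arr, fs = fs, layout = layout,
                 subject_id = subject_id),
            class = "raw_recording")
}

#' Write / read a stimulus schedule CSV
#'
#' Columns `onset_s`, `duration_s`, `condition`. Reading enforces the
#' schedule invariants (strictly increasing onsets).
#'
#' @param sch a `stim_schedule`.
#' @param path file path.
#' @return path / schedule.
#' @export
write_schedule_csv <- function(sch, path) {
  utils::write.csv(as.data.frame(sch), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$condition <- factor(df$condition, levels = c("forward", "reverse"))
  class(df) <- c("stim_schedule", "data.frame")
  validate_schedule(df)
  df
}

#' Write a per-subject epoch average as tidy CSV
#'
#' Columns: `subject`, `condition`, `channel`, `time_s`, `dHbO`, `dHbR`.
#'
#' @param ep an `epoch_average`.
#' @param subject subject identifier.
#' @param path file path.
#' @export
write_epochs_csv <- function(ep, subject, path) {
  rows <- list()
  for (cond in names(ep$conditions)) {
    if (is.null(ep$conditions[[cond]])) next
    m <- ep$conditions[[cond]]
    rows[[cond]] <- data.frame(
      subject = subject, condition = cond,
      channel = rep(ep$channel_id, each = length(ep$time_s)),
      time_s = rep(ep$time_s, length(ep$channel_id)),
      dHbO = c(m$hbo), dHbR = c(m$hbr))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs_csv
#' @param path file path.
#' @param layout probe layout used to re-attach hemispheres.
#' @return for `read_epochs_csv`, an `epoch_average` (trial counts are
#'   not stored in the tidy format and are set to `NA`).
#' @export
read_epochs_csv <- function(path, layout = probe_layout()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "channel", "time_s", "dHbO", "dHbR")
  if (!all(need %in% names(df)))
    stop("malformed epochs CSV ", path, call. = FALSE)
  time_s <- sort(unique(df$time_s))
  chans <- sort(unique(df$channel))
  conds <- list()
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond, ]
    hbo <- hbr <- matrix(NA_real_, length(time_s), length(chans))
    for (ci in seq_along(chans)) {
      s <- sub[sub$channel == chans[ci], ]
      o <- order(s$time_s)
      hbo[, ci] <- s$dHbO[o]; hbr[, ci] <- s$dHbR[o]
    }
    conds[[cond]] <- list(hbo = hbo, hbr = hbr)
  }
  fs <- 1 / stats::median(diff(time_s))
  structure(list(conditions = conds, time_s = time_s,
                 n_trials = stats::setNames(rep(NA_integer_, length(conds)),
                                            names(conds)),
                 n_total = stats::setNames(rep(NA_integer_, length(conds)),
                                           names(conds)),
                 channel_id = chans, layout = layout, fs = fs,
                 rejected = logical(), notes = character()),
            class = "epoch_average")
}

have_rhdf5 <- function() requireNamespace("rhdf5", quietly = TRUE)

#' Write / read a recording in SNIRF (HDF5) format
#'
#' Continuous-wave SNIRF: `/formatVersion`, `/nirs/data1/dataTimeSeries`
#' (time x measurements), `/nirs/data1/time`, one
#' `/nirs/data1/measurementList<i>` per measurement (source, detector,
#' wavelength index), and `/nirs/probe` with wavelengths and 2-D optode
#' positions (left-hemisphere sources at negative x). Requires the
#' `rhdf5` package.
#'
#' @param rec a `raw_recording`.
#' @param path `.snirf` file path.
#' @return path / `raw_recording`.
#' @export
write_snirf <- function(rec, path) {
  if (!have_rhdf5()) stop("SNIRF I/O needs the rhdf5 package", call. = FALSE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5 <- function(name, value) rhdf5::h5write(value, path, name)
  h5("formatVersion", "1.0")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  lay <- rec$layout
  wl <- layout_wavelengths(lay)
  n <- dim(rec$intensity)[1]; nch <- dim(rec$intensity)[2]
  dts <- matrix(0, n, nch * 2L)
  k <- 0L
  for (w in 1:2) for (ch in seq_len(nch)) {
    k <- k + 1L
    dts[, k] <- rec$intensity[, ch, w]
    g <- sprintf("nirs/data1/measurementList%d", k)
    rhdf5::h5createGroup(path, g)
    h5(paste0(g, "/sourceIndex"), as.integer(ch))
    h5(paste0(g, "/detectorIndex"), as.integer(ch))
    h5(paste0(g, "/wavelengthIndex"), as.integer(w))
    h5(paste0(g, "/dataType"), 1L)        # CW amplitude
    h5(paste0(g, "/dataTypeIndex"), 1L)
  }
  h5("nirs/data1/dataTimeSeries", dts)
  h5("nirs/data1/time", (seq_len(n) - 1) / rec$fs)
  rhdf5::h5createGroup(path, "nirs/probe")
  h5("nirs/probe/wavelengths", as.numeric(wl))
  xs <- ifelse(lay$hemisphere == "L", -5, 5)
  h5("nirs/probe/sourcePos2D", cbind(xs, seq_len(nch)))
  h5("nirs/probe/detectorPos2D", cbind(xs + lay$distance_cm, seq_len(nch)))
  h5("nirs/metaDataTags_SubjectID", rec$subject_id %||% "unknown")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_snirf
#' @param layout probe layout to attach on read (geometry checked
#'   against the file's hemispheres).
#' @export
read_snirf <- function(path, layout = probe_layout()) {
  if (!have_rhdf5()) stop("SNIRF I/O needs the rhdf5 package", call. = FALSE)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fv <- try(rhdf5::h5read(path, "formatVersion"), silent = TRUE)
  if (inherits(fv, "try-error"))
    stop("malformed SNIRF (missing /formatVersion): ", path, call. = FALSE)
  dts <- rhdf5::h5read(path, "nirs/data1/dataTimeSeries")
  tt <- as.numeric(rhdf5::h5read(path, "nirs/data1/time"))
  sid <- tryCatch(as.character(rhdf5::h5read(path, "nirs/metaDataTags_SubjectID")),
                  error = function(e) "unknown")
  rhdf5::h5closeAll()
  fs <- 1 / stats::median(diff(tt))
  nch <- ncol(dts) / 2L
  if (nch != nrow(layout))
    stop("channel count in ", path, " does not match layout", call. = FALSE)
  arr <- array(0, c(nrow(dts), nch, 2L))
  arr[, , 1L] <- dts[, seq_len(nch)]
  arr[, , 2L] <- dts[, nch + seq_len(nch)]
  structure(list(intensity = arr, fs = fs, layout = layout,
                 subject_id = sid),
            class = "raw_recording")
}

#' Run configuration
#'
#' A nested, YAML-serializable list that fully determines a pipeline
#' run together with the code version: master seed, probe/schedule
#' parameters, cohort sizes, noise levels, preprocessing parameters,
#' metric options and statistics options.
#'
#' @param seed master seed.
#' @param n_preterm,n_term cohort sizes.
#' @param probe,schedule,noise,outcome,preprocess,metrics,stats option
#'   lists; missing entries take the package defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_preterm = 26, n_term = 19,
                       probe = list(), schedule = list(), noise = list(),
                       truth = list(), outcome = list(), preprocess = list(),
                       metrics = list(response_window = c(0, 25),
                                      aggregation = "mean_first"),
                       stats = list(family_size = 16)) {
  cfg <- list(seed = seed, n_preterm = n_preterm, n_term = n_term,
              probe = probe, schedule = schedule, noise = noise,
              truth = truth, outcome = outcome, preprocess = preprocess,
              metrics = metrics, stats = stats)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- do.call(run_config, yaml::read_yaml(path))
  cfg
}

# deterministic polynomial rolling hash of the serialized config, for
# artifact fingerprinting
config_fingerprint <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
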