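# Synthetic-cohort generator: seeded two-wavelength recordings with
# known ground truth, plus language-outcome z-scores coupled to the
# designed laterality.

#' Physiological and motion noise configuration for the simulator
#'
#' Amplitudes of the concentration-domain physiological components are
#' in micromolar (applied to HbO; HbR receives `hbr_ratio` times the
#' amplitude); motion artifacts are added in the optical-density
#' domain, where the band-pass/motion-correction steps operate.
#' Frequencies are chosen so the 0.01--0.50 Hz band-pass removes the
#' cardiac component and most drift: slow drift well below 0.01 Hz,
#' a ~0.1 Hz low-frequency (Mayer-wave) oscillation, ~0.7 Hz
#' respiration, ~2.5 Hz cardiac pulsation.
#'
#' @param drift_amp,drift_freq slow-drift amplitude (uM) and frequency (Hz).
#' @param mayer_amp,mayer_freq low-frequency oscillation amplitude/frequency.
#' @param resp_amp,resp_freq respiratory component amplitude/frequency.
#' @param cardiac_amp,cardiac_freq cardiac component amplitude/frequency.
#' @param white_sd white measurement noise sd (uM per sample).
#' @param spike_rate,shift_rate expected motion artifacts per minute
#'   (Poisson counts): short additive spikes and step baseline shifts.
#' @param spike_amp_od,shift_amp_od amplitude ranges (OD units).
#' @param spike_dur_range spike duration range in seconds.
#' @param hbr_ratio HbR amplitude relative to HbO (signal uses
#'   `-hbr_ratio`, noise uses `hbr_ratio`).
#' @return a `noise_config` list.
#' @export
noise_config <- function(drift_amp = 0.5, drift_freq = 0.004,
                         mayer_amp = 0.2, mayer_freq = 0.1,
                         resp_amp = 0.15, resp_freq = 0.7,
                         cardiac_amp = 0.3, cardiac_freq = 2.5,
                         white_sd = 0.05,
                         spike_rate = 0.2, spike_amp_od = c(0.2, 1.0),
                         spike_dur_range = c(0.2, 1.0),
                         shift_rate = 0.02, shift_amp_od = c(0.2, 0.5),
                         hbr_ratio = 1 / 3) {
  cfg <- as.list(environment())
  if (any(vapply(cfg[c("drift_amp", "mayer_amp", "resp_amp", "cardiac_amp",
                       "white_sd", "spike_rate", "shift_rate")],
                 function(x) !is_scalar_num(x) || x < 0, logical(1))))
    abort_config("noise amplitudes and rates must be >= 0")
  class(cfg) <- "noise_config"
  cfg
}

#' Zero-noise configuration (for round-trip and oracle tests)
#' @return a `noise_config` with every component and artifact off.
#' @export
noise_off <- function() {
  noise_config(drift_amp = 0, mayer_amp = 0, resp_amp = 0, cardiac_amp = 0,
               white_sd = 0, spike_rate = 0, shift_rate = 0)
}

#' Ground truth for one simulated subject
#'
#' `sp_l` and `sp_r` are the designed per-hemisphere discrimination
#' amplitudes: the difference of mean window (0--25 s) HbO responses
#' between the forward and reverse condition, in micromolar. The
#' reverse condition responds at `base` uM in both hemispheres, the
#' forward condition at `base + sp_h`. Subjects with `sign = "inv"`
#' have the whole HbO response sign-flipped (and HbR, tied to HbO by
#' the negative `hbr_ratio`, flipped oppositely), emulating the
#' inverted responders seen in roughly half of neonates.
#'
#' @param sp_l,sp_r designed discrimination amplitude per hemisphere, uM (>= 0).
#' @param base reverse-condition response level, uM (default 0.10).
#' @param sign `"pos"` or `"inv"`.
#' @param group `"preterm"` or `"term"`.
#' @param seed integer; drives every random draw for this subject.
#' @param subject_id identifier string.
#' @return a `subject_truth` list with the amplitude matrix `amp`
#'   (condition x hemisphere window-mean response, uM) and `true_li`.
#' @export
subject_truth <- function(sp_l, sp_r, base = 0.10, sign = c("pos", "inv"),
                          group = c("term", "preterm"), seed = 1,
                          subject_id = "s01") {
  sign <- match.arg(sign)
  group <- match.arg(group)
  if (sp_l < 0 || sp_r < 0) abort_config("sp_l and sp_r must be >= 0")
  amp <- matrix(c(base + sp_l, base + sp_r, base, base), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("forward", "reverse"), c("L", "R")))
  if (sign == "inv") amp <- -amp
  true_li <- if (sp_l + sp_r > 0) (sp_l - sp_r) / (sp_l + sp_r) * 100 else NA_real_
  structure(list(amp = amp, sp_l = sp_l, sp_r = sp_r, base = base,
                 sign = sign, group = group, true_li = true_li,
                 seed = as.integer(seed), subject_id = subject_id),
            class = "subject_truth")
}

#' Simulate one raw two-wavelength fNIRS recording
#'
#' Forward model: designed window-mean amplitudes are converted to
#' kernel amplitudes, block boxcars are convolved with a single-gamma
#' hemodynamic kernel, physiological noise is added in concentration
#' space, concentrations are mapped to optical density through the same
#' extinction/DPF/distance model the inverse step uses, motion
#' artifacts (spikes and step shifts) are added in OD, and intensity is
#' formed as `I = i0 * 10^(-dOD)`.
#'
#' @param truth a [subject_truth()].
#' @param layout a [probe_layout()].
#' @param schedule a [make_schedule()] schedule.
#' @param noise a [noise_config()] (default: realistic levels).
#' @param fs sampling rate, Hz (default 10).
#' @param i0 baseline intensity (arbitrary units, > 0).
#' @param age subject age in years for the DPF (default 0).
#' @param tail_s recording time after the last block, seconds.
#' @param extinction optional extinction matrix override.
#' @param hrf_peak kernel time-to-peak, seconds.
#' @return a `raw_recording`: list with `intensity` (samples x channels
#'   x 2 wavelengths), `fs`, `layout`, `subject_id`, and attribute
#'   `truth_conc` holding the latent noise-free concentration series.
#' @export
simulate_subject <- function(truth, layout = probe_layout(),
                             schedule = make_schedule(seed = truth$seed),
                             noise = noise_config(), fs = 10, i0 = 1,
                             age = 0, tail_s = 35, extinction = NULL,
                             hrf_peak = 7) {
  if (!is_scalar_num(i0) || i0 <= 0)
    abort_config("baseline intensity i0 must be > 0")
  validate_schedule(schedule)
  n <- ceiling((schedule_end_s(schedule) + tail_s) * fs)
  nch <- nrow(layout)
  k <- block_window_mean(schedule$duration_s[1], fs, time_to_peak = hrf_peak)

  hemi <- layout$hemisphere
  hbo <- matrix(0, n, nch)
  for (cond in levels(schedule$condition)) {
    on <- schedule$onset_s[schedule$condition == cond]
    if (!length(on)) next
    reg <- block_regressor(on, schedule$duration_s[1], n, fs,
                           time_to_peak = hrf_peak)
    hbo <- hbo + outer(reg, truth$amp[cond, hemi] / k)
  }
  hbr <- -noise$hbr_ratio * hbo
  truth_conc <- structure(list(hbo = hbo, hbr = hbr, fs = fs, layout = layout,
                               channel_id = layout$channel_id),
                          class = "conc_series")

  rec <- with_seed(truth$seed, {
    tt <- (seq_len(n) - 1) / fs
    phys <- function(amp_scale) {
      out <- matrix(0, n, nch)
      for (ch in seq_len(nch)) {
        comp <- numeric(n)
        for (p in list(c(noise$drift_amp, noise$drift_freq),
                       c(noise$mayer_amp, noise$mayer_freq),
                       c(noise$resp_amp, noise$resp_freq),
                       c(noise$cardiac_amp, noise$cardiac_freq))) {
          if (p[1] > 0) {
            f <- p[2] * stats::runif(1, 0.9, 1.1)
            comp <- comp + p[1] * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
          }
        }
        if (noise$white_sd > 0) comp <- comp + stats::rnorm(n, 0, noise$white_sd)
        out[, ch] <- amp_scale * comp
      }
      out
    }
    hbo_n <- hbo + phys(1)
    hbr_n <- hbr + phys(noise$hbr_ratio)
    dod <- conc_to_od(hbo_n, hbr_n, layout, age, extinction)

    minutes <- n / fs / 60
    for (ch in seq_len(nch)) {
      art <- numeric(n)
      n_spk <- stats::rpois(1, noise$spike_rate * minutes)
      if (n_spk > 0) for (s in seq_len(n_spk)) {
        at <- sample.int(n, 1)
        dur <- round(stats::runif(1, noise$spike_dur_range[1],
                                  noise$spike_dur_range[2]) * fs)
        amp <- stats::runif(1, noise$spike_amp_od[1], noise$spike_amp_od[2]) *
          sample(c(-1, 1), 1)
        idx <- at:min(n, at + max(dur, 1L) - 1L)
        # half-sine spike profile
        art[idx] <- art[idx] + amp * sin(pi * seq_along(idx) / (length(idx) + 1))
      }
      n_sh <- stats::rpois(1, noise$shift_rate * minutes)
      if (n_sh > 0) for (s in seq_len(n_sh)) {
        at <- sample.int(n, 1)
        amp <- stats::runif(1, noise$shift_amp_od[1], noise$shift_amp_od[2]) *
          sample(c(-1, 1), 1)
        art[at:n] <- art[at:n] + amp
      }
      dod[, ch, 1L] <- dod[, ch, 1L] + art
      dod[, ch, 2L] <- dod[, ch, 2L] + art
    }
    intensity <- i0 * 10^(-dod)
    structure(list(intensity = intensity, fs = fs, layout = layout,
                   subject_id = truth$subject_id),
              class = "raw_recording")
  })
  attr(rec, "truth_conc") <- truth_conc
  attr(rec, "schedule") <- schedule
  rec
}

#' Group-level truth distributions for cohort simulation
#'
#' Defaults are per-hemisphere discrimination amplitude means/sds (uM,
#' truncated at zero) matching the descriptive cohort statistics the
#' generator is designed to emulate (term-born larger than preterm),
#' and an inverted-responder fraction of 49/92.
#'
#' @param preterm,term lists with `sp_l = c(mean, sd)` and
#'   `sp_r = c(mean, sd)`.
#' @param p_inverted probability of an inverted HbO response.
#' @param base reverse-condition response level (uM).
#' @return a `truth_distributions` list.
#' @export
cohort_truth_defaults <- function(preterm = list(sp_l = c(0.10, 0.09),
                                                 sp_r = c(0.11, 0.09)),
                                  term = list(sp_l = c(0.17, 0.14),
                                              sp_r = c(0.15, 0.12)),
                                  p_inverted = 49 / 92, base = 0.10) {
  for (g in list(preterm, term))
    for (p in g)
      if (length(p) != 2 || p[2] < 0)
        abort_config("truth distribution entries must be c(mean, sd >= 0)")
  if (p_inverted < 0 || p_inverted > 1)
    abort_config("p_inverted must be in [0, 1]")
  structure(list(preterm = preterm, term = term,
                 p_inverted = p_inverted, base = base),
            class = "truth_distributions")
}

rtrunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmax(mean, 0), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Language-outcome model
#'
#' Phonological short-term memory (STM) z-scores are coupled to the
#' designed laterality index: `z_stm = mean_g + slope * (LI/100) +
#' noise`. Sentence-production and morphological-rules z-scores share a
#' configured mutual rank correlation; comprehension is independent.
#' Group-specific means/sds default to values typical of a mixed
#' preterm/term follow-up cohort. `slope` and `noise_sd` defaults are
#' calibrated so the implied population rank correlation between STM
#' and LI is `target_rs` (see [implied_outcome_rank_cor()]).
#'
#' @param slope STM coupling slope on LI/100.
#' @param noise_sd residual sd of the STM score.
#' @param target_rs design rank correlation of STM with LI (recorded,
#'   used by tests as the design value).
#' @param rs_sent_morph design rank correlation between sentence
#'   production and morphological rules.
#' @param means,sds named lists per group of length-4 numeric vectors
#'   (comprehension, sentence, morphology, stm).
#' @return an `outcome_model` list.
#' @export
outcome_model <- function(slope = 1, noise_sd = 0.78, target_rs = 0.5,
                          rs_sent_morph = 0.52,
                          means = list(preterm = c(0.31, -0.21, -0.25, 0.07),
                                       term = c(0.47, 0.42, 0.11, 0.21)),
                          sds = list(preterm = c(1.03, 1.22, 1.37, 1.26),
                                     term = c(1.15, 0.76, 1.04, 1.23))) {
  if (noise_sd < 0) abort_config("noise_sd must be >= 0")
  if (abs(rs_sent_morph) > 1) abort_config("rs_sent_morph must be in [-1, 1]")
  if (any(unlist(sds) < 0)) abort_config("outcome sds must be >= 0")
  structure(list(slope = slope, noise_sd = noise_sd, target_rs = target_rs,
                 rs_sent_morph = rs_sent_morph, means = means, sds = sds),
            class = "outcome_model")
}

#' Generate language-outcome z-scores from designed laterality
#'
#' @param true_li per-subject designed laterality indices in [-100, 100].
#' @param group character vector, `"preterm"`/`"term"`, recycled.
#' @param model an [outcome_model()].
#' @param seed integer seed.
#' @return data frame with columns `z_comprehension`, `z_sentence`,
#'   `z_morphology`, `z_stm`.
#' @export
generate_outcomes <- function(true_li, group = "term",
                              model = outcome_model(), seed = 1) {
  li <- true_li
  if (any(!is.na(li) & abs(li) > 100))
    abort_config("true_li values must lie in [-100, 100]")
  n <- length(li)
  group <- rep(group, length.out = n)
  with_seed(seed, {
    m <- do.call(rbind, model$means[group])
    s <- do.call(rbind, model$sds[group])
    z_comp <- stats::rnorm(n, m[, 1], s[, 1])
    # sentence/morphology pair with designed mutual rank correlation
    rho <- 2 * sin(pi * model$rs_sent_morph / 6) # Pearson for normal copula
    u1 <- stats::rnorm(n); u2 <- rho * u1 + sqrt(1 - rho^2) * stats::rnorm(n)
    z_sent <- m[, 2] + s[, 2] * u1
    z_morph <- m[, 3] + s[, 3] * u2
    z_stm <- m[, 4] + model$slope * (ifelse(is.na(li), 0, li) / 100) +
      stats::rnorm(n, 0, model$noise_sd)
    data.frame(z_comprehension = z_comp, z_sentence = z_sent,
               z_morphology = z_morph, z_stm = z_stm)
  })
}

#' Monte-Carlo estimate of the implied STM--laterality rank correlation
#'
#' Draws a large synthetic population from the truth distributions and
#' outcome model and returns the empirical Spearman correlation between
#' designed laterality and the STM z-score: the generator's realized
#' design value for the coupling.
#'
#' @param truth_dist a [cohort_truth_defaults()].
#' @param model an [outcome_model()].
#' @param n population size (default 2e5).
#' @param seed integer seed.
#' @param group group to draw (mixture if `"both"`, default).
#' @return scalar rank correlation.
#' @export
implied_outcome_rank_cor <- function(truth_dist = cohort_truth_defaults(),
                                     model = outcome_model(), n = 2e5,
                                     seed = 99, group = "both") {
  li <- with_seed(seed, {
    g <- if (group == "both")
      sample(c("preterm", "term"), n, replace = TRUE) else rep(group, n)
    sl <- numeric(n); sr <- numeric(n)
    for (gg in unique(g)) {
      i <- g == gg
      sl[i] <- rtrunc0(sum(i), truth_dist[[gg]]$sp_l[1], truth_dist[[gg]]$sp_l[2])
      sr[i] <- rtrunc0(sum(i), truth_dist[[gg]]$sp_r[1], truth_dist[[gg]]$sp_r[2])
    }
    list(li = (sl - sr) / (sl + sr) * 100, g = g)
  })
  out <- generate_outcomes(li$li, li$g, model, seed = seed + 1)
  stats::cor(li$li, out$z_stm, method = "spearman", use = "complete.obs")
}

#' Simulate a labelled cohort of recordings and outcomes
#'
#' Draws per-subject ground truth from group-specific distributions,
#' generates language outcomes coupled to the designed laterality, and
#' (optionally) synthesizes the raw recordings.
#'
#' @param n_preterm,n_term group sizes (total >= 2).
#' @param truth_dist a [cohort_truth_defaults()].
#' @param model an [outcome_model()].
#' @param seed integer master seed; subject seeds derive from it.
#' @param recordings if `TRUE` (default) simulate raw recordings; if
#'   `FALSE` return truths and the cohort table only (fast path for
#'   outcome-level Monte-Carlo studies).
#' @param layout,noise,fs forwarded to [simulate_subject()].
#' @param schedule_args list of arguments for [make_schedule()]; each
#'   subject gets its own seeded schedule (counterbalanced paradigm).
#' @return list with `truths` (list of `subject_truth`), `recordings`
#'   (list of `raw_recording` or `NULL`), `schedules`, and `cohort`
#'   (data frame: ids, group, sex, gestational age, SES, designed
#'   metrics, outcome z-scores).
#' @export
simulate_cohort <- function(n_preterm = 26, n_term = 19,
                            truth_dist = cohort_truth_defaults(),
                            model = outcome_model(), seed = 1,
                            recordings = TRUE, layout = probe_layout(),
                            noise = noise_config(), fs = 10,
                            schedule_args = list()) {
  if (!is_count(n_preterm) || !is_count(n_term) || n_preterm + n_term < 2)
    abort_config("need n_preterm + n_term >= 2")
  n <- n_preterm + n_term
  group <- c(rep("preterm", n_preterm), rep("term", n_term))

  draws <- with_seed(seed, {
    sl <- numeric(n); sr <- numeric(n)
    for (gg in unique(group)) {
      i <- group == gg
      sl[i] <- rtrunc0(sum(i), truth_dist[[gg]]$sp_l[1], truth_dist[[gg]]$sp_l[2])
      sr[i] <- rtrunc0(sum(i), truth_dist[[gg]]$sp_r[1], truth_dist[[gg]]$sp_r[2])
    }
    list(
      sl = sl, sr = sr,
      sign = ifelse(stats::runif(n) < truth_dist$p_inverted, "inv", "pos"),
      sex = sample(c("f", "m"), n, replace = TRUE),
      ga = ifelse(group == "preterm", stats::runif(n, 25, 34),
                  stats::runif(n, 37, 42)),
      edu_m = sample(1:5, n, replace = TRUE),
      edu_f = sample(1:5, n, replace = TRUE),
      income = sample(1:8, n, replace = TRUE),
      subj_seed = sample.int(2^31 - 2, n)
    )
  })

  ids <- sprintf("s%03d", seq_len(n))
  truths <- lapply(seq_len(n), function(i)
    subject_truth(draws$sl[i], draws$sr[i], base = truth_dist$base,
                  sign = draws$sign[i], group = group[i],
                  seed = draws$subj_seed[i], subject_id = ids[i]))
  true_li <- vapply(truths, `[[`, numeric(1), "true_li")
  outcomes <- generate_outcomes(true_li, group, model, seed = seed + 1)

  schedules <- recs <- NULL
  if (recordings) {
    schedules <- lapply(seq_len(n), function(i)
      do.call(make_schedule, utils::modifyList(list(seed = draws$subj_seed[i]),
                                               schedule_args)))
    recs <- lapply(seq_len(n), function(i)
      simulate_subject(truths[[i]], layout, schedules[[i]], noise, fs = fs))
  }

  cohort <- data.frame(
    subject_id = ids, group = group, sex = draws$sex,
    gestational_age = draws$ga,
    ses = mapply(ses_composite, draws$edu_m, draws$edu_f, draws$income),
    sign = draws$sign,
    true_sp_l = draws$sl, true_sp_r = draws$sr, true_li = true_li,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, outcomes)
  list(truths = truths, recordings = recs, schedules = schedules,
       cohort = cohort)
}
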