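# Orchestration: simulate -> preprocess -> metrics -> stats as one
# reproducible, logged run.

#' Compute the metrics table for a list of preprocessed subjects
#'
#' @param pps list of [preprocess_recording()] results.
#' @param response_window,aggregation metric options.
#' @return data frame with one [subject_metrics()] row per subject.
#' @export
metrics_table <- function(pps, response_window = c(0, 25),
                          aggregation = "mean_first") {
  do.call(rbind, lapply(pps, subject_metrics,
                        response_window = response_window,
                        aggregation = aggregation))
}

# per-subject condition x hemisphere HbO means, long format, for the
# mixed ANOVA
anova_cells <- function(pps, groups, response_window = c(0, 25)) {
  rows <- list()
  for (i in seq_along(pps)) {
    pp <- pps[[i]]
    if (!pp$inclusion$included) next
    cm <- condition_mean(pp$epochs, response_window = response_window)
    lay <- pp$epochs$layout
    for (cond in colnames(cm)) for (h in c("L", "R")) {
      sel <- pp$epochs$channel_id %in% channels_of(lay, h)
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = pp$subject_id, group = groups[i], condition = cond,
        hemisphere = h, value = mean(cm[sel, cond]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cohort statistics report
#'
#' Runs the statistical battery on a merged metrics/covariates table:
#' normality screen per metric, mixed 2x2x2 ANOVA (when cell data are
#' supplied), group comparisons of each metric (two-sample t, both
#' tails, plus Mann-Whitney U), the metric-by-outcome Spearman grid
#' with a Bonferroni family, and slope-homogeneity tests of the
#' laterality--STM coupling across groups.
#'
#' @param cohort data frame with `group`, metric columns (`sp`, `sp_l`,
#'   `sp_r`, `li_sp`) and outcome z-score columns.
#' @param cells optional long cell data for [mixed_anova_2x2x2()].
#' @param family_size Bonferroni family for the correlation grid.
#' @return list `normality`, `anova`, `group_tests`, `correlations`,
#'   `slope_tests`, `text` (human-readable report lines).
#' @export
cohort_report <- function(cohort, cells = NULL, family_size = 16) {
  metrics <- intersect(c("sp", "sp_l", "sp_r", "li_sp"), names(cohort))
  outcomes <- intersect(c("z_comprehension", "z_sentence", "z_morphology",
                          "z_stm"), names(cohort))
  norm <- do.call(rbind, lapply(metrics, function(m) {
    x <- cohort[[m]][is.finite(cohort[[m]])]
    k <- if (length(x) >= 5 && stats::sd(x) > 0) ks_normality(x)
    else list(statistic = NA, p = NA)
    data.frame(metric = m, D = k$statistic, p = k$p, n = length(x))
  }))

  an <- if (!is.null(cells)) mixed_anova_2x2x2(cells) else NULL

  gt <- do.call(rbind, lapply(metrics, function(m) {
    x <- cohort[[m]][cohort$group == "preterm" & is.finite(cohort[[m]])]
    y <- cohort[[m]][cohort$group == "term" & is.finite(cohort[[m]])]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(metric = m, t = NA, p_two = NA, p_one = NA,
                        U = NA, p_mw = NA))
    tt <- two_sample_t(y, x)     # term minus preterm, matching reporting
    mw <- mann_whitney_u(y, x)
    data.frame(metric = m, t = tt$t, p_two = tt$p_two, p_one = tt$p_one,
               U = mw$U, p_mw = mw$p)
  }))

  ct <- if (length(outcomes))
    corr_table(cohort, metrics, outcomes, family_size = family_size)
  else NULL

  st <- if ("z_stm" %in% outcomes && all(c("li_sp", "sp_r") %in% metrics)) {
    do.call(rbind, lapply(c("li_sp", "sp_r"), function(m) {
      ok <- is.finite(cohort[[m]]) & is.finite(cohort$z_stm)
      if (min(table(cohort$group[ok])) < 3)
        return(data.frame(metric = m, F = NA, p = NA))
      s <- slope_homogeneity(cohort$z_stm[ok], cohort[[m]][ok],
                             cohort$group[ok])
      data.frame(metric = m, F = s$F, p = s$p)
    }))
  } else NULL

  text <- c(
    sprintf("Cohort: %d subjects (%d preterm, %d term)", nrow(cohort),
            sum(cohort$group == "preterm"), sum(cohort$group == "term")),
    "Group comparisons (two-sample t, term vs preterm; both tails reported; p_one is one-tailed):",
    sprintf("  %-6s t = %6.2f  p(two) = %.3f  p(one) = %.3f", gt$metric,
            gt$t, gt$p_two, gt$p_one))
  if (!is.null(ct)) {
    sig <- ct[ct$significant, , drop = FALSE]
    text <- c(text,
              sprintf("Correlation grid: %d pairs, Bonferroni alpha = %.6f",
                      nrow(ct), 0.05 / family_size),
              if (nrow(sig)) sprintf("  %s x %s: r_s = %.2f (p = %.4g) *",
                                     sig$metric, sig$outcome, sig$estimate, sig$p)
              else "  no pair survives the Bonferroni family")
  }
  list(normality = norm, anova = an, group_tests = gt, correlations = ct,
       slope_tests = st, text = text)
}

#' Run the full pipeline on a configuration
#'
#' Simulates the cohort, preprocesses every recording, computes
#' per-subject metrics, runs the cohort statistics, and writes all
#' artifacts (config copy, cohort/metrics/ANOVA/correlation CSVs,
#' per-subject exclusion log, human-readable report) to `out_dir`.
#' A run is fully determined by `(config, code version)`; the config
#' fingerprint is embedded in every artifact directory.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @return list: `cohort` (merged table), `metrics`, `report`,
#'   `log` (data frame of exclusions), `fingerprint`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  fp <- config_fingerprint(config)
  sim <- simulate_cohort(
    config$n_preterm, config$n_term,
    truth_dist = do.call(cohort_truth_defaults, config$truth %||% list()),
    model = do.call(outcome_model, config$outcome %||% list()),
    seed = config$seed, recordings = TRUE,
    layout = do.call(probe_layout, config$probe %||% list()),
    noise = do.call(noise_config, config$noise %||% list()),
    schedule_args = config$schedule %||% list())

  pcfg <- do.call(preprocess_config, config$preprocess %||% list())
  pps <- lapply(sim$recordings, preprocess_recording, config = pcfg)

  mt <- metrics_table(pps,
                      response_window = config$metrics$response_window %||% c(0, 25),
                      aggregation = config$metrics$aggregation %||% "mean_first")
  cohort <- merge(sim$cohort, mt, by = "subject_id", sort = TRUE)

  n_in <- nrow(sim$cohort)
  n_excl <- sum(!cohort$included)
  stopifnot(n_in == n_excl + sum(cohort$included))  # no silent data loss

  log <- do.call(rbind, lapply(pps, function(pp) {
    if (pp$inclusion$included) return(NULL)
    data.frame(subject_id = pp$subject_id, stage = "inclusion",
               rule = paste(pp$inclusion$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  if (is.null(log)) log <- data.frame(subject_id = character(),
                                      stage = character(), rule = character())

  cells <- anova_cells(pps, sim$cohort$group,
                       config$metrics$response_window %||% c(0, 25))
  rep <- cohort_report(cohort[cohort$included, , drop = FALSE], cells,
                       family_size = config$stats$family_size %||% 16)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    utils::write.csv(cohort, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(log, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
    if (!is.null(rep$anova))
      utils::write.csv(rep$anova, file.path(out_dir, "anova.csv"), row.names = FALSE)
    if (!is.null(rep$correlations))
      utils::write.csv(rep$correlations, file.path(out_dir, "correlations.csv"),
                       row.names = FALSE)
    writeLines(c(sprintf("config fingerprint: %s", fp), rep$text),
               file.path(out_dir, "report.txt"))
  }
  list(cohort = cohort, metrics = mt, report = rep, log = log,
       fingerprint = fp, preprocessed = pps)
}
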