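# Shared fixture builders. Everything is generated in code; no files.

# minimal od_series wrapper around a samples x channels x wavelengths array
make_od <- function(dod, fs = 10, layout = NULL) {
  if (is.null(layout))
    layout <- probe_layout(n_channels = dim(dod)[2])
  structure(list(dod = dod, fs = fs, layout = layout,
                 channel_id = layout$channel_id),
            class = "od_series")
}

# single-channel od_series from a vector (duplicated across 2 wavelengths)
make_od1 <- function(x, fs = 10) {
  dod <- array(0, c(length(x), 2, 2))
  dod[, 1, 1] <- x; dod[, 1, 2] <- x
  dod[, 2, 1] <- 0; dod[, 2, 2] <- 0
  make_od(dod, fs, probe_layout(n_channels = 2))
}

# tiny epoch_average built directly from per-channel condition means:
# constant-in-time epochs so window means equal the supplied values
make_epochs <- function(fwd, rev, layout = probe_layout(n_channels = length(fwd)),
                        fs = 10, window = c(-2, 25)) {
  time_s <- seq(window[1], window[2] - 1 / fs, by = 1 / fs)
  n <- length(time_s)
  mk <- function(v) list(hbo = matrix(rep(v, each = n), n, length(v)),
                         hbr = matrix(rep(-v / 3, each = n), n, length(v)),
                         n_channel_trials = rep(10L, length(v)))
  structure(list(conditions = list(forward = mk(fwd), reverse = mk(rev)),
                 time_s = time_s,
                 n_trials = c(forward = 10L, reverse = 10L),
                 n_total = c(forward = 10L, reverse = 10L),
                 channel_id = layout$channel_id, layout = layout, fs = fs,
                 rejected = logical(20), notes = character()),
            class = "epoch_average")
}

# balanced long-format cell data for the mixed ANOVA
make_cells <- function(n_per_group = 6, seed = 1, effects = list()) {
  set.seed(seed)
  d <- expand.grid(subject = seq_len(2 * n_per_group),
                   condition = c("forward", "reverse"),
                   hemisphere = c("L", "R"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject <= n_per_group, "preterm", "term")
  d$value <- rnorm(nrow(d))
  for (e in names(effects)) {
    if (e == "condition") d$value <- d$value +
        ifelse(d$condition == "forward", effects[[e]], 0)
    if (e == "cxhxg") d$value <- d$value + effects[[e]] *
        ifelse(d$condition == "forward", 1, -1) *
        ifelse(d$hemisphere == "L", 1, -1) *
        ifelse(d$group == "term", 1, -1)
  }
  d
}

# independent brute-force sums-of-squares partition for the balanced
# 2 (group) x 2 (condition) x 2 (hemisphere) mixed design
oracle_mixed_ss <- function(d) {
  y <- xtabs(value ~ subject + condition + hemisphere, d)
  grp <- tapply(d$group, d$subject, function(g) g[1])
  grp <- stats::setNames(as.character(grp[rownames(y)]), rownames(y))
  N <- nrow(y); gm <- mean(y)
  yS  <- apply(y, 1, mean)
  yB  <- apply(y, 2, mean)
  yC  <- apply(y, 3, mean)
  yA  <- vapply(split(yS, grp), mean, numeric(1))
  ySB <- apply(y, c(1, 2), mean)
  ySC <- apply(y, c(1, 3), mean)
  yBC <- apply(y, c(2, 3), mean)
  yAB <- t(vapply(names(yA), function(g) apply(y[grp == g, , , drop = FALSE],
                                               2, mean), numeric(2)))
  yAC <- t(vapply(names(yA), function(g) apply(y[grp == g, , , drop = FALSE],
                                               3, mean), numeric(2)))
  yABC <- array(0, c(2, 2, 2), dimnames = list(names(yA), dimnames(y)[[2]],
                                               dimnames(y)[[3]]))
  for (g in names(yA)) yABC[g, , ] <- apply(y[grp == g, , , drop = FALSE],
                                            c(2, 3), mean)
  ng <- stats::setNames(as.numeric(table(grp)[names(yA)]), names(yA))
  ss <- list()
  ss$group      <- 4 * sum(ng * (yA - gm)^2)
  ss$subj       <- 4 * sum((yS - yA[grp])^2)
  ss$condition  <- 2 * N * sum((yB - gm)^2)
  ss$cxg        <- 2 * sum(ng * rowSums((sweep(sweep(yAB, 1, yA), 2, yB) + gm)^2))
  dev <- ySB - outer(yS, rep(1, 2)) - yAB[grp, ] + yA[grp]
  ss$bs         <- 2 * sum(dev^2)
  ss$hemisphere <- 2 * N * sum((yC - gm)^2)
  ss$hxg        <- 2 * sum(ng * rowSums((sweep(sweep(yAC, 1, yA), 2, yC) + gm)^2))
  dev <- ySC - outer(yS, rep(1, 2)) - yAC[grp, ] + yA[grp]
  ss$cs         <- 2 * sum(dev^2)
  ss$cxh        <- N * sum((sweep(sweep(yBC, 1, yB), 2, yC) + gm)^2)
  dev_abc <- yABC
  for (g in names(yA)) for (b in 1:2) for (cc in 1:2)
    dev_abc[g, b, cc] <- yABC[g, b, cc] - yAB[g, b] - yAC[g, cc] - yBC[b, cc] +
      yA[g] + yB[b] + yC[cc] - gm
  ss$cxhxg <- sum(vapply(names(yA), function(g)
    ng[g] * sum(dev_abc[g, , ]^2), numeric(1)))
  res <- 0
  for (s in rownames(y)) for (b in 1:2) for (cc in 1:2) {
    g <- as.character(grp[s])
    res <- res + (y[s, b, cc] - ySB[s, b] - ySC[s, cc] - yABC[g, b, cc] +
                    yS[s] + yAB[g, b] + yAC[g, cc] - yA[g])^2
  }
  ss$bcs <- res
  lapply(ss, function(v) unname(as.numeric(v)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
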