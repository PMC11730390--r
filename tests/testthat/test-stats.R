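test_that("Lilliefors screen accepts normal and rejects uniform samples", {
  accept <- vapply(1:100, function(s) {
    set.seed(s); ks_normality(rnorm(200))$p > 0.05
  }, logical(1))
  expect_gte(mean(accept), 0.90)

  set.seed(1)
  expect_lt(ks_normality(runif(500))$p, 0.05)

  # statistic equals the max ECDF deviation from the fitted normal
  set.seed(2)
  x <- rnorm(60)
  d <- ks_normality(x)$statistic
  xs <- sort(x); n <- length(x)
  cdf <- pnorm(xs, mean(x), sd(x))
  d_loop <- max(pmax(abs(seq_len(n) / n - cdf), abs(cdf - (seq_len(n) - 1) / n)))
  expect_equal(d, d_loop, tolerance = 1e-12)

  expect_true(ks_normality(rep(1, 10))$degenerate)
  expect_error(ks_normality(1:3), "n >= 5")
})

test_that("identical cells give zero F throughout the mixed ANOVA", {
  d <- make_cells(n_per_group = 4, seed = 1)
  d$value <- 1
  a <- mixed_anova_2x2x2(d)
  expect_true(all(a$F == 0))
  expect_true(all(a$pes == 0))
})

test_that("mixed ANOVA matches brute-force SS and contrast-t oracles", {
  for (s in 1:30) {
    d <- make_cells(n_per_group = 6, seed = s)
    a <- mixed_anova_2x2x2(d)
    ss <- oracle_mixed_ss(d)
    N <- 12
    Fo <- c(group = (ss$group) / (ss$subj / (N - 2)),
            condition = (ss$condition) / (ss$bs / (N - 2)),
            `group:condition` = (ss$cxg) / (ss$bs / (N - 2)),
            hemisphere = (ss$hemisphere) / (ss$cs / (N - 2)),
            `group:hemisphere` = (ss$hxg) / (ss$cs / (N - 2)),
            `condition:hemisphere` = (ss$cxh) / (ss$bcs / (N - 2)),
            `group:condition:hemisphere` = (ss$cxhxg) / (ss$bcs / (N - 2)))
    expect_equal(a$F[match(names(Fo), a$effect)], unname(Fo),
                 tolerance = 1e-8)
    # partial eta squared from the same partition
    pes3 <- ss$cxhxg / (ss$cxhxg + ss$bcs)
    expect_equal(a$pes[a$effect == "group:condition:hemisphere"], pes3,
                 tolerance = 1e-8)
    # SS decomposition completeness
    expect_equal(sum(unlist(ss)), sum((d$value - mean(d$value))^2),
                 tolerance = 1e-8)
    # three-way F equals the squared two-sample t on the double contrast
    y <- xtabs(value ~ subject + condition + hemisphere, d)
    grp <- as.character(tapply(d$group, d$subject, `[`, 1)[rownames(y)])
    ctr <- (y[, 1, 1] - y[, 1, 2]) - (y[, 2, 1] - y[, 2, 2])
    t3 <- t.test(ctr[grp == "term"], ctr[grp == "preterm"],
                 var.equal = TRUE)$statistic
    expect_equal(unname(t3^2),
                 a$F[a$effect == "group:condition:hemisphere"],
                 tolerance = 1e-8)
  }
})

test_that("subjects with missing cells are dropped with a record", {
  d <- make_cells(n_per_group = 4, seed = 2)
  d <- d[!(d$subject == 1 & d$condition == "forward" & d$hemisphere == "L"), ]
  a <- mixed_anova_2x2x2(d)
  expect_equal(attr(a, "dropped"), "1")
})

test_that("t tests report both tails and handle degenerate input", {
  p <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(p$t, 0)
  expect_equal(p$p_two, 1)
  expect_equal(p$flag, "zero variance")

  # textbook two-sample case, hand-computed pooled t
  tt <- two_sample_t(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(tt$t, -1.8973665961, tolerance = 1e-9)
  expect_equal(tt$p_two, 0.0943497728, tolerance = 1e-9)
  expect_equal(tt$p_one, tt$p_two / 2)

  set.seed(3)
  x <- rnorm(12); y <- rnorm(12, 0.5)
  pt_ <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(pt_$t, unname(ref$statistic))
  expect_equal(pt_$p_one, ref$p.value / 2)
})

test_that("Mann-Whitney U covers symmetric, extreme and exact cases", {
  x <- c(1, 1, 2, 2); y <- c(1, 1, 2, 2)
  m <- mann_whitney_u(x, y)
  expect_equal(m$U, length(x) * length(y) / 2)

  m2 <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_true(m2$U %in% c(0, 9))

  # exact p matches brute-force enumeration of group assignments
  x <- c(1.2, 3.4, 2.2); y <- c(5.1, 0.3, 6.2, 4.4)
  m3 <- mann_whitney_u(x, y)
  all_v <- c(x, y)
  combs <- utils::combn(7, 3)
  u_obs <- m3$U
  u_all <- apply(combs, 2, function(idx) {
    r <- rank(all_v)
    sum(r[idx]) - 3 * 4 / 2
  })
  # two-sided exact p: extremeness of |U - n1 n2 / 2|
  p_exact <- mean(abs(u_all - 6) >= abs(u_obs - 6) - 1e-9)
  expect_equal(m3$p, p_exact, tolerance = 1e-9)
  expect_equal(m3$method, "exact")
})

test_that("Spearman equals Pearson on average ranks, with sensible p", {
  expect_equal(spearman(1:10, (1:10)^3)$estimate, 1)
  expect_equal(spearman(1:10, -(1:10))$estimate, -1)

  # tied data against the rank-then-Pearson covariance loop
  x <- c(1, 2, 2, 3, 5, 5, 7, 8, 9, 10, 11, 3)
  y <- c(2, 1, 4, 4, 6, 7, 7, 9, 8, 12, 11, 5)
  s <- spearman(x, y)
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(s$estimate, num / den, tolerance = 1e-12)

  # t-approximation p agrees with cor.test for larger n
  set.seed(4)
  x <- rnorm(40); y <- x + rnorm(40)
  s2 <- spearman(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(s2$estimate, unname(ref$estimate), tolerance = 1e-12)

  # small-sample exact permutation p against a direct enumeration oracle
  set.seed(5)
  x <- rnorm(6); y <- rnorm(6)
  s3 <- spearman(x, y)
  rx <- rank(x)
  perms <- neonirs:::all_perms(6)
  rs_all <- apply(perms, 2, function(p) cor(rx, p))
  rs_obs <- cor(rank(x), rank(y))
  p_exact <- mean(abs(rs_all) >= abs(rs_obs) - 1e-9)
  expect_equal(s3$p, p_exact, tolerance = 1e-9)

  expect_true(is.na(spearman(rep(1, 6), rnorm(6))$estimate))
})

test_that("Bonferroni families flag at 0.05 / family size", {
  tab <- data.frame(p = c(0.04, 0.002, 0.0035, NA))
  out1 <- bonferroni_family(tab, 1)
  expect_equal(out1$significant, c(TRUE, TRUE, TRUE, FALSE))
  out16 <- bonferroni_family(tab, 16)
  expect_equal(out16$alpha_bonferroni[1], 0.003125)
  expect_equal(out16$significant, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("correlation grid applies the family over all cells", {
  set.seed(6)
  n <- 45
  df <- data.frame(sp = rnorm(n), sp_l = rnorm(n), sp_r = rnorm(n),
                   li_sp = rnorm(n))
  df$z_stm <- 2 * df$li_sp + rnorm(n, 0, 0.1)      # one strong pair
  df$z_comprehension <- rnorm(n)
  df$z_sentence <- rnorm(n)
  df$z_morphology <- rnorm(n)
  ct <- corr_table(df)
  expect_equal(nrow(ct), 16)
  expect_equal(unique(ct$family_size), 16)
  expect_true(all(ct$significant == (ct$p < 0.003125), na.rm = TRUE))
  expect_true(ct$significant[ct$metric == "li_sp" & ct$outcome == "z_stm"])
})

test_that("slope homogeneity detects designed slope differences", {
  set.seed(7)
  n <- 200
  g <- rep(c("a", "b"), each = n)
  x <- rnorm(2 * n)
  y <- ifelse(g == "a", 1, -1) * x + rnorm(2 * n, 0, 0.5)
  s <- slope_homogeneity(y, x, g)
  expect_lt(s$p, 0.001)

  # F matches the nested-model SSE comparison
  d <- data.frame(y = y, x = x, g = g)
  f0 <- lm(y ~ g + x, d); f1 <- lm(y ~ g + x + g:x, d)
  sse0 <- sum(resid(f0)^2); sse1 <- sum(resid(f1)^2)
  Fo <- ((sse0 - sse1) / 1) / (sse1 / f1$df.residual)
  expect_equal(s$F, Fo, tolerance = 1e-8)

  # identical slopes: p should not be systematically small
  set.seed(8)
  ps <- vapply(1:60, function(k) {
    x <- rnorm(120); g <- rep(c("a", "b"), each = 60)
    y <- x + rnorm(120)
    slope_homogeneity(y, x, g)$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.85)   # near-nominal type-I control
})

test_that("SES composite follows the printed rescaling formula", {
  expect_equal(ses_composite(5, 5, 8), 5)
  expect_equal(ses_composite(1, 1, 1), 1)
  expect_equal(ses_composite(3, 4, 5), 3.4285714286, tolerance = 1e-9)
  expect_error(ses_composite(0, 3, 4), "education")
  expect_error(ses_composite(3, 3, 9), "income")
})

test_that("z-score classification uses the clinical boundaries", {
  expect_equal(as.character(classify_z(0)), "average")
  expect_equal(as.character(classify_z(-2)), "below_average")
  expect_equal(as.character(classify_z(-2.89)), "reduced")
  expect_equal(as.character(classify_z(c(1, 1.01, -1, -1.01))),
               c("average", "above_average", "average", "below_average"))
  expect_error(classify_z(NA), "finite")
})
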