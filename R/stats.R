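# Cohort-level statistics: normality screening, mixed 2x2x2
# repeated-measures ANOVA with partial eta squared, t tests,
# Mann-Whitney U, Spearman/Pearson correlation with Bonferroni
# families, slope homogeneity, the SES composite, and z-score
# classification.

#' Kolmogorov-Smirnov (Lilliefors) normality screen
#'
#' One-sample KS test against a normal with mean and sd estimated from
#' the sample, using the Lilliefors correction of the null
#' distribution (via `nortest::lillie.test`).
#'
#' @param x numeric sample, n >= 5.
#' @return list `statistic`, `p`, `degenerate` (TRUE for a constant
#'   sample, where the test is undefined).
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need n >= 5", call. = FALSE)
  if (stats::sd(x) == 0)
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  lt <- nortest::lillie.test(x)
  list(statistic = unname(lt$statistic), p = unname(lt$p.value),
       degenerate = FALSE)
}

#' Mixed 2x2x2 repeated-measures ANOVA with partial eta squared
#'
#' Within-subject factors condition (forward/reverse) and hemisphere
#' (left/right), between-subjects factor group (preterm/term); the
#' standard mixed-design partition (subjects nested in group, separate
#' error strata for each within effect) via `stats::aov` with `Error()`
#' strata. Partial eta squared is SS_effect / (SS_effect + SS_error of
#' the effect's stratum).
#'
#' @param cells long data frame with columns `subject`, `group`,
#'   `condition`, `hemisphere`, `value`; one value per subject x
#'   condition x hemisphere cell. Subjects with missing cells are
#'   dropped (recorded in attribute `dropped`).
#' @return data frame: `effect`, `df1`, `df2`, `F`, `p`, `pes`.
#' @export
mixed_anova_2x2x2 <- function(cells) {
  need <- c("subject", "group", "condition", "hemisphere", "value")
  if (!all(need %in% names(cells)))
    stop("cells must have columns ", paste(need, collapse = ", "), call. = FALSE)
  cells$subject <- factor(cells$subject)
  cells$group <- factor(cells$group)
  cells$condition <- factor(cells$condition)
  cells$hemisphere <- factor(cells$hemisphere)
  cnt <- table(cells$subject)
  bad <- names(cnt)[cnt != 4L]
  if (length(bad)) cells <- droplevels(cells[!(cells$subject %in% bad), ])
  if (nlevels(cells$group) < 2)
    stop("both groups must be nonempty", call. = FALSE)

  fit <- stats::aov(value ~ group * condition * hemisphere +
                      Error(subject / (condition * hemisphere)), data = cells)
  s <- summary(fit)
  ss_tot <- sum((cells$value - mean(cells$value))^2)
  out <- data.frame(effect = character(), df1 = numeric(), df2 = numeric(),
                    F = numeric(), p = numeric(), pes = numeric(),
                    stringsAsFactors = FALSE)
  for (stratum in s) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    ri <- which(rn == "Residuals")
    if (!length(ri)) next
    ss_err <- tab[ri, "Sum Sq"]; df_err <- tab[ri, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), ri)) {
      ss <- tab[i, "Sum Sq"]
      Fv <- tab[i, "F value"]; pv <- tab[i, "Pr(>F)"]
      # an effect with no sum of squares at the data scale has F = 0;
      # aov reports 0/0 artifacts on exactly degenerate input
      if (ss_tot < 1e-20 || ss / ss_tot < 1e-12) { ss <- 0; Fv <- 0; pv <- 1 }
      if (!is.finite(Fv)) { Fv <- 0; pv <- 1 }
      out <- rbind(out, data.frame(
        effect = rn[i], df1 = tab[i, "Df"], df2 = df_err,
        F = Fv, p = pv,
        pes = if (ss + ss_err > 0) ss / (ss + ss_err) else 0,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- bad
  out
}

#' Paired and two-sample t tests with explicit tail convention
#'
#' Thin wrappers over `stats::t.test` that report the statistic with
#' both the two-sided and the one-sided (in the direction of the
#' observed effect) p-value; zero-variance inputs are flagged instead
#' of erroring.
#'
#' @param x,y numeric samples (for `paired_t`, matched pairs).
#' @return list `t`, `df`, `p_two`, `p_one`, `flag`.
#' @export
paired_t <- function(x, y) {
  d <- x - y
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = length(d) - 1,
                p_two = if (t == 0) 1 else 0,
                p_one = if (t == 0) 0.5 else 0,
                flag = "zero variance"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two = tt$p.value, p_one = tt$p.value / 2, flag = NULL)
}

#' @rdname paired_t
#' @param var_equal assume equal variances (classical two-sample t,
#'   default TRUE, matching standard reporting).
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    t <- if (d == 0) 0 else sign(d) * Inf
    return(list(t = t, df = length(x) + length(y) - 2,
                p_two = if (t == 0) 1 else 0,
                p_one = if (t == 0) 0.5 else 0,
                flag = "zero variance"))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two = tt$p.value, p_one = tt$p.value / 2, flag = NULL)
}

#' Mann-Whitney U test
#'
#' Reports U, the tie-corrected normal-approximation z, and a p-value:
#' exact (via the null distribution of U) when `min(n1, n2) <= 8` and
#' there are no ties, the normal approximation otherwise.
#'
#' @param x,y numeric samples.
#' @param tails `"two"` (default) or `"one"`.
#' @return list `U`, `z`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U <- min(U1, n1 * n2 - U1)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  z <- if (sigma == 0) 0 else (U1 - n1 * n2 / 2) / sigma
  has_ties <- any(ties > 1)
  if (min(n1, n2) <= 8 && !has_ties) {
    # exact two-sided p: extremeness of |U - n1 n2 / 2| under the exact
    # null distribution of U
    m <- n1 * n2 / 2
    u_all <- 0:(n1 * n2)
    pr <- stats::dwilcox(u_all, n1, n2)
    p <- sum(pr[abs(u_all - m) >= abs(U1 - m) - 1e-9])
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  if (tails == "one") p <- p / 2
  list(U = unname(U1), z = unname(z), p = unname(p), method = method)
}

#' Spearman rank correlation
#'
#' `r_s` is the Pearson correlation of average-ranked data. The
#' p-value uses the t approximation
#' \eqn{t = r_s\sqrt{(n-2)/(1-r_s^2)}}; for n < 10 without ties, an
#' exact permutation p-value is computed by full enumeration.
#'
#' @param x,y numeric vectors (pairs with missing values dropped).
#' @return list `estimate`, `p`, `n`, `method`.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(estimate = NA_real_, p = NA_real_, n = n,
                method = "undefined (zero variance)"))
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(x) || anyDuplicated(y)
  if (n < 10 && !has_ties) {
    d2_obs <- sum((rx - ry)^2)
    perms <- all_perms(n)
    d2 <- colSums((perms - rx)^2)   # rx fixed, ry permuted uniformly
    # two-sided on |r_s| <=> extremeness of |d2 - E[d2]|
    ed2 <- n * (n^2 - 1) / 6
    p <- mean(abs(d2 - ed2) >= abs(d2_obs - ed2) - 1e-9)
    method <- "exact permutation"
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(estimate = unname(rs), p = unname(p), n = n, method = method)
}

# all permutations of 1..n as an n x n! matrix (n <= 9)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (pos in seq_len(n)) {
    block <- rbind(sub, 0L)
    if (pos < n) block[(pos + 1):n, ] <- sub[pos:(n - 1), , drop = FALSE]
    block[pos, ] <- n
    out[, col + seq_len(ncol(sub))] <- block
    col <- col + ncol(sub)
  }
  out
}

#' Pearson correlation with t-based p-value
#' @param x,y numeric vectors.
#' @return list `estimate`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(estimate = NA_real_, p = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y)
  list(estimate = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Apply a Bonferroni family to a correlation table
#'
#' Flags each pair significant iff `p < 0.05 / family_size`.
#'
#' @param tab data frame with a `p` column.
#' @param family_size number of tests in the family (>= 1).
#' @return `tab` with columns `alpha_bonferroni`, `family_size`,
#'   `significant`.
#' @export
bonferroni_family <- function(tab, family_size) {
  if (!is_count(family_size) || family_size < 1)
    abort_config("family_size must be >= 1")
  tab$alpha_bonferroni <- 0.05 / family_size
  tab$family_size <- family_size
  tab$significant <- !is.na(tab$p) & tab$p < 0.05 / family_size
  tab
}

#' Metric-by-outcome correlation table
#'
#' Pairwise correlations (Spearman by default, matching non-normal
#' outcome scores) between every metric and every outcome column, with
#' pairwise deletion of missing values and a Bonferroni family over
#' all cells (default family size = number of cells, e.g. 16 for a
#' 4 x 4 grid).
#'
#' @param df data frame holding both sets of columns.
#' @param metrics,outcomes column-name character vectors.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param family_size Bonferroni family (default
#'   `length(metrics) * length(outcomes)`).
#' @return data frame: `metric`, `outcome`, `estimate`, `p`, `n`,
#'   Bonferroni columns.
#' @export
corr_table <- function(df, metrics = c("sp", "sp_l", "sp_r", "li_sp"),
                       outcomes = c("z_comprehension", "z_sentence",
                                    "z_morphology", "z_stm"),
                       method = c("spearman", "pearson"),
                       family_size = length(metrics) * length(outcomes)) {
  method <- match.arg(method)
  fun <- if (method == "spearman") spearman else pearson
  rows <- list()
  for (m in metrics) for (o in outcomes) {
    r <- fun(df[[m]], df[[o]])
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, outcome = o, estimate = r$estimate, p = r$p, n = r$n,
      stringsAsFactors = FALSE)
  }
  bonferroni_family(do.call(rbind, rows), family_size)
}

#' Slope homogeneity across groups
#'
#' F-test of the group-by-covariate interaction in the linear model
#' `outcome ~ group + covariate + group:covariate` (the univariate
#' ANOVA fixed factor-by-covariate interaction).
#'
#' @param outcome,covariate numeric vectors.
#' @param group factor-like group labels (2+ levels, each n >= 3).
#' @return list `F`, `df1`, `df2`, `p`, `flag`.
#' @export
slope_homogeneity <- function(outcome, covariate, group) {
  group <- factor(group)
  if (any(table(group) < 3)) stop("each group needs n >= 3", call. = FALSE)
  d <- data.frame(outcome = outcome, covariate = covariate, group = group)
  d <- d[stats::complete.cases(d), ]
  fit <- stats::lm(outcome ~ group + covariate + group:covariate, data = d)
  if (anyNA(stats::coef(fit)))
    return(list(F = NA_real_, df1 = NA, df2 = NA, p = NA_real_,
                flag = "collinear"))
  a <- stats::anova(fit)
  i <- which(rownames(a) == "group:covariate")
  list(F = a[i, "F value"], df1 = a[i, "Df"], df2 = a["Residuals", "Df"],
       p = a[i, "Pr(>F)"], flag = NULL)
}

#' Socioeconomic-status composite
#'
#' Arithmetic mean of maternal education (1--5), paternal education
#' (1--5), and household income rescaled from its 8-point scale to
#' 5 points as `(income - 1) * 4/7 + 1`.
#'
#' @param edu_mother,edu_father integers 1--5.
#' @param income integer 1--8.
#' @return SES composite on the 1--5 scale.
#' @export
ses_composite <- function(edu_mother, edu_father, income) {
  if (edu_mother < 1 || edu_mother > 5 || edu_father < 1 || edu_father > 5)
    stop("education levels must be on the 1-5 scale", call. = FALSE)
  if (income < 1 || income > 8)
    stop("income must be on the 1-8 scale", call. = FALSE)
  mean(c(edu_mother, edu_father, (income - 1) * 4 / 7 + 1))
}

#' Classify a language z-score against clinical conventions
#'
#' `z > 1` above average; `-1 <= z <= 1` average; `-2 <= z < -1` below
#' average; `z < -2` (strictly) reduced — a score of exactly -2 counts
#' as below average.
#'
#' @param z finite numeric vector.
#' @return factor with levels `above_average`, `average`,
#'   `below_average`, `reduced`.
#' @export
classify_z <- function(z) {
  if (any(!is.finite(z))) stop("z-scores must be finite", call. = FALSE)
  out <- ifelse(z < -2, "reduced",
         ifelse(z < -1, "below_average",
         ifelse(z <= 1, "average", "above_average")))
  factor(out, levels = c("above_average", "average", "below_average", "reduced"))
}
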