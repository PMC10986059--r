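#' Percent change of a metric from pre to post
#'
#' `100 * (post - pre) / pre`, the percentage change of a choroidal metric
#' induced by a near-work session.
#'
#' @param pre,post numeric vectors (recycled); `pre` must be non-zero.
#' @return percent change, same length as the longer input.
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stopf("percent change is undefined for pre = 0")
  100 * (post - pre) / pre
}

#' Paired pre/post change test
#'
#' One-sample t-test of the per-subject change scores against zero.
#'
#' @param deltas numeric vector of per-subject post-minus-pre changes
#'   (n >= 2, not all identical).
#' @return list with `t`, `df`, `p`, `mean`, `sd`, `n`.
#' @export
paired_change_test <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  n <- length(deltas)
  if (n < 2L) stopf("paired test needs at least 2 change scores")
  if (sd(deltas) == 0) stopf("all change scores are identical; t is undefined")
  ht <- t.test(deltas, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(deltas), sd = sd(deltas), n = n)
}

#' Bonferroni adjustment for m comparisons
#'
#' @param p vector of raw p values.
#' @param m number of comparisons in the family (defaults to `length(p)`).
#' @return adjusted p values, `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) stopf("m must be >= 1")
  pmin(1, m * p)
}

# Box's Greenhouse-Geisser epsilon from the sample covariance of the k
# within-subject levels; clamped to its theoretical range [1/(k-1), 1].
gg_epsilon <- function(S) {
  k <- ncol(S)
  if (k == 2L) return(1)
  d_bar <- mean(diag(S))
  s_bar <- mean(S)
  row_means <- rowMeans(S)
  denom <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * s_bar^2)
  if (denom <= .Machine$double.eps) return(1)
  eps <- (k * (d_bar - s_bar))^2 / denom
  min(1, max(1 / (k - 1), eps))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One within-subject factor with k levels on n subjects (complete cases
#' required). The within-subject F is `MS_time / MS_(time x subject)`;
#' sphericity is corrected by multiplying both degrees of freedom by Box's
#' epsilon estimated from the sample covariance of the k levels, and the
#' p value is taken from the F distribution at the adjusted df.
#'
#' @param wide numeric matrix or data.frame, one row per subject, one
#'   column per within-subject level; n > k required.
#' @return list of class `rm_anova_result`: `F`, `df1`, `df2`
#'   (GG-adjusted), `epsilon_gg`, `p`, plus unadjusted `df1_unadj`,
#'   `df2_unadj`.
#' @export
rm_anova_gg <- function(wide) {
  x <- as.matrix(wide)
  if (anyNA(x)) stopf("missing cells; repeated-measures ANOVA needs complete cases")
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2L) stopf("need at least 2 within-subject levels")
  if (n <= k) stopf("need more subjects (%d) than levels (%d)", n, k)
  grand <- mean(x)
  col_m <- colMeans(x)
  row_m <- rowMeans(x)
  ss_time <- n * sum((col_m - grand)^2)
  resid <- x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  if (ss_time <= .Machine$double.eps) {
    f_stat <- 0
  } else {
    ms_err <- ss_err / df2
    if (ms_err <= .Machine$double.eps)
      stopf("zero within-subject error variance with a non-zero time effect")
    f_stat <- (ss_time / df1) / ms_err
  }
  eps <- gg_epsilon(stats::cov(x))
  p <- if (f_stat == 0) 1 else pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE)
  structure(list(F = f_stat, df1 = eps * df1, df2 = eps * df2,
                 epsilon_gg = eps, p = p,
                 df1_unadj = df1, df2_unadj = df2, n = n, k = k),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%.2f, %.2f) = %.3f, GG epsilon = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$epsilon_gg, x$p))
  invisible(x)
}

#' Axial-length-adjusted group contrast of near-work changes
#'
#' Linear model of the per-subject percent changes on cohort membership and
#' axial length (plus a sum-coded duration factor and its interaction with
#' group when several durations are supplied), with a cluster-robust
#' (sandwich) variance by subject. With sum coding the group coefficient is
#' the AL-adjusted mean difference of changes (second group minus first)
#' averaged over durations.
#'
#' @param change numeric vector of per-subject-visit percent changes.
#' @param group factor/character of cohort labels (exactly 2 levels).
#' @param al_mm axial length per observation, mm.
#' @param duration optional duration label per observation.
#' @param subject cluster identifier per observation (defaults to row index,
#'   i.e. independent observations).
#' @return list of class `group_contrast`: `estimate` (adjusted mean
#'   difference), `se`, `t`, `p`, `covariates`, `n`.
#' @export
group_contrast_ancova <- function(change, group, al_mm,
                                  duration = NULL, subject = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2L) stopf("group must have exactly 2 levels")
  df <- data.frame(change = change, group = group, al_mm = al_mm)
  if (nrow(df) < 4L) stopf("need at least 4 observations")
  if (is.null(subject)) subject <- seq_len(nrow(df))
  df$subject <- factor(subject)
  drop_al <- var(df$al_mm) <= .Machine$double.eps
  if (drop_al)
    warning("axial length has zero variance; covariate dropped", call. = FALSE)
  has_dur <- !is.null(duration) && length(unique(duration)) > 1L
  if (has_dur) {
    df$duration <- factor(duration)
    stats::contrasts(df$duration) <- stats::contr.sum(nlevels(df$duration))
    form <- if (drop_al) change ~ group * duration else change ~ group * duration + al_mm
  } else {
    form <- if (drop_al) change ~ group else change ~ group + al_mm
  }
  fit <- lm(form, data = df)
  vc <- sandwich::vcovCL(fit, cluster = df$subject)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  term <- paste0("group", levels(group)[2])
  structure(list(estimate = unname(coef(fit)[term]),
                 se = ct[term, "Std. Error"],
                 t = ct[term, "t value"],
                 p = ct[term, "Pr(>|t|)"],
                 covariates = if (drop_al) character() else "al_mm",
                 groups = levels(group),
                 n = nrow(df),
                 fit = fit),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("Adjusted mean difference (%s - %s) = %.3f (SE %.3f), p = %.4g\n",
              x$groups[2], x$groups[1], x$estimate, x$se, x$p))
  invisible(x)
}

#' Intraclass correlation, two-way absolute agreement, single measure
#'
#' ICC(A,1) from the two-way ANOVA mean squares of an n-subjects by
#' k-measurements table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#'
#' @param x,y two repeated measurement series of equal length (n >= 3), or
#'   `x` a matrix with one column per measurement and `y` missing.
#' @return ICC estimate (scalar).
#' @export
icc_absolute_agreement <- function(x, y = NULL) {
  m <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  if (anyNA(m)) stopf("missing values in the repeatability series")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L) stopf("need at least 3 subjects")
  grand <- mean(m)
  if (sum((m - grand)^2) <= .Machine$double.eps)
    stopf("zero total variance; ICC is undefined")
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Bland-Altman agreement statistics
#'
#' @param x,y two measurement series of equal length.
#' @return list with `bias` (mean of `y - x`), `loa_low`, `loa_high`
#'   (bias -/+ 1.96 SD of the differences) and `sd_diff`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stopf("series lengths differ")
  d <- y - x
  s <- sd(d)
  list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s, sd_diff = s)
}
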