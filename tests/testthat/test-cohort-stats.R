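test_that("percent change is the pre-anchored relative change", {
  expect_equal(percent_change(250, 250), 0)
  expect_equal(percent_change(990.0, 970.8), 100 * (970.8 - 990.0) / 990.0)
  expect_error(percent_change(0, 10), "pre = 0")
  set.seed(1)
  pre <- runif(50, 10, 300)
  post <- pre + rnorm(50, 0, 20)
  expect_identical(sign(percent_change(pre, post)), sign(post - pre))
})

test_that("paired change test matches the closed-form t computation", {
  sym <- c(-2, 2, -0.5, 0.5)
  r <- paired_change_test(sym)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  x <- c(-3, -1, -4, -2, -5)
  r2 <- paired_change_test(x)
  # brute-force oracle from the t formula and CDF
  m <- sum(x) / 5
  s <- sqrt(sum((x - m)^2) / 4)
  t_oracle <- m / (s / sqrt(5))
  expect_equal(r2$t, t_oracle, tolerance = 1e-12)
  expect_equal(r2$p, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)

  expect_error(paired_change_test(c(1)), "at least 2")
  expect_error(paired_change_test(rep(2, 5)), "identical")
})

test_that("bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.4, 3), 1.0)
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(c(0.01, 0.4)), c(0.02, 0.8))
  expect_identical(bonferroni_adjust(c(0.02, 0.4)),
                   p.adjust(c(0.02, 0.4), method = "bonferroni"))
})

test_that("greenhouse-geisser epsilon honours its bounds and k = 2 identity", {
  set.seed(5)
  r <- rm_anova_gg(matrix(rnorm(40), 20, 2))
  expect_identical(r$epsilon_gg, 1)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    x <- matrix(rnorm(15 * k), 15, k) %*% matrix(rnorm(k * k), k)
    rr <- rm_anova_gg(x)
    expect_gte(rr$epsilon_gg, 1 / (k - 1))
    expect_lte(rr$epsilon_gg, 1)
    expect_gte(rr$p, 0)
    expect_lte(rr$p, 1)
  }
})

test_that("epsilon approaches 1 under compound symmetry", {
  set.seed(7)
  n <- 300
  k <- 4
  subj <- rnorm(n, 0, 2)
  x <- outer(subj, rep(1, k)) + matrix(rnorm(n * k), n, k)
  r <- rm_anova_gg(x)
  expect_lt(abs(r$epsilon_gg - 1), 0.05)
})

test_that("constant-over-time data give a zero F", {
  x <- outer(rnorm(12), rep(1, 3))
  r <- rm_anova_gg(x)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  expect_error(rm_anova_gg(matrix(rnorm(6), 2, 3)), "more subjects")
  xm <- matrix(rnorm(30), 10, 3)
  xm[2, 3] <- NA
  expect_error(rm_anova_gg(xm), "complete")
})

test_that("rm anova agrees with the multivariate GG route", {
  set.seed(13)
  x <- matrix(rnorm(25 * 3, mean = rep(c(0, 0.4, 0.1), each = 25)), 25, 3)
  x <- x + outer(rnorm(25, 0, 1.5), rep(1, 3))
  r <- rm_anova_gg(x)
  # independent oracle: car's repeated-measures machinery
  suppressMessages(library(car))
  idata <- data.frame(time = factor(1:3))
  fit <- lm(x ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = ~time, type = 3)
  # car warns about its Huynh-Feldt column (eps > 1); only GG is compared
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  gg_eps <- s$pval.adjustments["time", "GG eps"]
  gg_p <- s$pval.adjustments["time", "Pr(>F[GG])"]
  expect_equal(r$epsilon_gg, unname(gg_eps), tolerance = 1e-6)
  expect_equal(r$p, unname(gg_p), tolerance = 1e-6)
})

test_that("group contrast recovers an injected effect and matches least squares", {
  set.seed(21)
  n <- 40
  al <- rep(rnorm(n, 24.5, 1), 2)          # same AL values in both groups
  grp <- rep(c("adult", "child"), each = n)
  delta <- 2.0
  change <- rnorm(2 * n, 0, 1) + ifelse(grp == "child", delta, 0)
  gc <- group_contrast_ancova(change, grp, al)
  expect_lt(abs(gc$estimate - delta), 0.6)
  expect_lt(gc$p, 0.001)

  # identical distributions, zero-variance AL: covariate dropped with warning
  expect_warning(
    gc0 <- group_contrast_ancova(rnorm(2 * n), grp, rep(24.5, 2 * n)),
    "zero variance")
  expect_lt(abs(gc0$estimate), 0.5)

  # 8-row toy design against the normal equations
  ch <- c(1.2, 0.8, 1.5, 0.9, 2.2, 2.6, 1.9, 2.4)
  gg <- rep(c("a", "b"), each = 4)
  aa <- c(24.1, 24.9, 25.3, 23.8, 24.2, 25.1, 24.7, 24.0)
  gc8 <- group_contrast_ancova(ch, gg, aa)
  X <- cbind(1, gg == "b", aa)
  beta <- solve(t(X) %*% X, t(X) %*% ch)
  expect_equal(gc8$estimate, beta[2], tolerance = 1e-9)
})

test_that("ICC and Bland-Altman behave on degenerate and shifted series", {
  x <- c(10, 12, 15, 11, 14, 13)
  expect_equal(icc_absolute_agreement(x, x), 1)
  ba <- bland_altman(x, x + 3)
  expect_equal(ba$bias, 3)
  expect_equal(ba$loa_low, 3)
  expect_equal(ba$loa_high, 3)
  expect_error(icc_absolute_agreement(rep(5, 6), rep(5, 6)), "undefined")
  expect_error(icc_absolute_agreement(x[1:2], x[1:2]), "at least 3")
})

test_that("ICC matches the variance-components ratio in simulation", {
  set.seed(31)
  n <- 500
  subj <- rnorm(n, 0, 3)                 # between-subject variance 9
  y1 <- subj + rnorm(n, 0, 1)            # error variance 1
  y2 <- subj + rnorm(n, 0, 1)
  icc <- icc_absolute_agreement(y1, y2)
  expect_lt(abs(icc - 9 / 10), 0.05)
})
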