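# From-scratch balanced two-way ANOVA decomposition (cell-means formulas).
oracle_balanced_anova <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y) / (nlevels(a) * nlevels(b))
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ss_a <- n * nlevels(b) * sum((ma - gm)^2)
  ss_b <- n * nlevels(a) * sum((mb - gm)^2)
  ss_ab <- n * sum((sweep(sweep(mab, 1, ma), 2, mb) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab,
       ss_res = ss_tot - ss_a - ss_b - ss_ab, ss_tot = ss_tot)
}

test_that("two-way ANOVA reproduces the factorial df structure", {
  set.seed(1)
  # 38 animals in a 2x2 design -> residual df 34 regardless of imbalance
  a <- rep(c("-", "+"), c(18, 20))
  b <- c(rep(c("-", "+"), c(9, 9)), rep(c("-", "+"), c(10, 10)))
  tab <- two_way_anova(rnorm(38), a, b)
  expect_equal(tab$df[4], 34)
  expect_equal(tab$df[1:3], c(1, 1, 1))
})

test_that("two-way ANOVA handles the degenerate all-equal response", {
  a <- rep(c("-", "+"), each = 6); b <- rep(c("-", "+"), 6)
  tab <- two_way_anova(rep(5, 12), a, b)
  expect_equal(tab$statistic[1:3], c(0, 0, 0))
  expect_equal(tab$p_value[1:3], c(1, 1, 1))
})

test_that("balanced two-way ANOVA matches the cell-means decomposition", {
  set.seed(7)
  for (rep in 1:5) {
    a <- rep(c("x", "y"), each = 10)
    b <- rep(rep(c("u", "v"), each = 5), 2)
    y <- rnorm(20, mean = 2 * (a == "y") + (b == "v"))
    tab <- two_way_anova(y, a, b)
    want <- oracle_balanced_anova(y, a, b)
    expect_equal(tab$sum_sq, c(want$ss_a, want$ss_b, want$ss_ab, want$ss_res),
                 tolerance = 1e-10)
    # conservation of total SS
    expect_equal(sum(tab$sum_sq), want$ss_tot, tolerance = 1e-9)
    ms_res <- want$ss_res / tab$df[4]
    expect_equal(tab$statistic[1], (want$ss_a / 1) / ms_res, tolerance = 1e-10)
  }
})

test_that("two-way ANOVA is invariant to observation order and validates input", {
  set.seed(17)
  a <- rep(c("-", "+"), each = 8); b <- rep(c("-", "+"), 8); y <- rnorm(16)
  t1 <- two_way_anova(y, a, b)
  o <- sample(16)
  t2 <- two_way_anova(y[o], a[o], b[o])
  expect_equal(t1$sum_sq, t2$sum_sq, tolerance = 1e-10)

  expect_error(two_way_anova(y[1:8], a[1:8], rep("-", 8)), "two levels")
  expect_error(
    two_way_anova(c(1, 2, 3), c("-", "-", "+"), c("-", "+", "-")),
    "empty design cell")
})

test_that("one-way ANOVA df, degenerate case and two-group identity", {
  set.seed(27)
  g <- rep(1:3, each = 10)
  tab <- one_way_anova(rnorm(30), g)
  expect_equal(tab$df, c(2, 27))

  tid <- one_way_anova(rep(c(4, 4, 4), 4), rep(1:3, 4))
  expect_equal(tid$statistic[1], 0); expect_equal(tid$p_value[1], 1)

  # two groups: F equals the squared pooled-variance t statistic
  x <- rnorm(12); y <- rnorm(10, 0.5)
  f <- one_way_anova(c(x, y), rep(1:2, c(12, 10)))$statistic[1]
  t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
  expect_equal(f, unname(t2), tolerance = 1e-12)

  expect_error(one_way_anova(1:3, c(1, 1, 2)), "residual")
})

test_that("Welch's t matches its defining formulas", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  expect_equal(welch_t(x, x)$t, 0)
  expect_equal(welch_t(x, x)$p, 1)

  # exactly equal variances and n: df collapses to n_a + n_b - 2
  y <- x + 2.5
  expect_equal(welch_t(x, y)$df, length(x) + length(y) - 2)

  set.seed(37)
  a <- rnorm(9); b <- rnorm(14, 1, 2)
  got <- welch_t(a, b)
  se <- sqrt(var(a) / 9 + var(b) / 14)
  t_want <- (mean(b) - mean(a)) / se
  df_want <- se^4 / ((var(a) / 9)^2 / 8 + (var(b) / 14)^2 / 13)
  expect_equal(got$t, t_want, tolerance = 1e-12)
  expect_equal(got$df, df_want, tolerance = 1e-12)
  expect_equal(got$p, 2 * stats::pt(-abs(t_want), df_want), tolerance = 1e-12)

  expect_error(welch_t(1, c(1, 2)), "two observations")
})

test_that("Sidak adjustment follows its closed form and monotonicity", {
  expect_equal(sidak_adjust(0), 0)
  expect_equal(sidak_adjust(1), 1)
  expect_equal(sidak_adjust(0.01, m = 2), 1 - 0.99^2)

  p_grid <- seq(0, 1, by = 0.05)
  for (m in c(1, 2, 4, 8)) {
    adj <- vapply(p_grid, sidak_adjust, numeric(1), m = m)
    expect_true(all(diff(adj) >= -1e-15))        # monotone in p
    expect_true(all(adj >= p_grid - 1e-15))       # never decreases
    if (m > 1) {
      prev <- vapply(p_grid, sidak_adjust, numeric(1), m = m - 1)
      expect_true(all(adj >= prev - 1e-15))       # monotone in family size
    }
  }
  expect_error(sidak_adjust(1.2), "0, 1")
  expect_error(sidak_adjust(c(0.1, 0.2, 0.3), m = 2), "family size")
})

test_that("BCa bootstrap handles degenerate input and symmetric reduction", {
  est <- bca_ci(rep(2, 5), rep(3.5, 5), seed = 1)
  expect_equal(est$mean_difference, 1.5)
  expect_equal(est$ci_low, 1.5); expect_equal(est$ci_high, 1.5)
  expect_true(est$degenerate)

  # when z0 = 0 and a = 0 the BCa endpoints are the plain percentiles
  set.seed(47)
  g1 <- rnorm(40); g2 <- rnorm(40, 1)
  est2 <- bca_ci(g1, g2, n_boot = 4000, seed = 12)
  # recompute the bootstrap distribution deterministically for the same seed
  boot_stat <- phagoquant:::with_seed(12, {
    m1 <- colMeans(matrix(sample(g1, 40 * 4000, TRUE), 40))
    m2 <- colMeans(matrix(sample(g2, 40 * 4000, TRUE), 40))
    m2 - m1
  })
  zhat <- est2$z0; ahat <- est2$acceleration
  zq <- qnorm(c(0.025, 0.975))
  probs <- pnorm(zhat + (zhat + zq) / (1 - ahat * (zhat + zq)))
  want <- phagoquant:::norm_inter(boot_stat, probs)
  expect_equal(c(est2$ci_low, est2$ci_high), want, tolerance = 1e-12)

  # groups with symmetric jackknife influence: acceleration is exactly 0 and
  # the BCa probabilities reduce towards the plain percentile levels
  s1 <- c(-2, -1, 1, 2); s2 <- c(3, 4, 6, 7)
  es <- bca_ci(s1, s2, n_boot = 2000, seed = 9)
  expect_equal(es$acceleration, 0)
  red <- pnorm(es$z0 + (es$z0 + zq))
  boot_sym <- phagoquant:::with_seed(9, {
    m1 <- colMeans(matrix(sample(s1, 4 * 2000, TRUE), 4))
    m2 <- colMeans(matrix(sample(s2, 4 * 2000, TRUE), 4))
    m2 - m1
  })
  expect_equal(c(es$ci_low, es$ci_high),
               phagoquant:::norm_inter(boot_sym, red), tolerance = 1e-12)
})

test_that("BCa agrees with the boot package and t-theory on normal data", {
  skip_if_not_installed("boot")
  set.seed(57)
  g1 <- rnorm(30); g2 <- rnorm(30, 0.8)
  mine <- bca_ci(g1, g2, n_boot = 9999, seed = 3)

  dat <- data.frame(y = c(g1, g2), g = rep(1:2, each = 30))
  bt <- boot::boot(dat, function(d, i) {
    di <- d[i, ]; mean(di$y[di$g == 2]) - mean(di$y[di$g == 1])
  }, R = 9999, strata = dat$g)
  ci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  width <- mine$ci_high - mine$ci_low
  expect_lt(abs(mine$ci_low - ci[1]), 0.1 * width)
  expect_lt(abs(mine$ci_high - ci[2]), 0.1 * width)

  # asymptotic agreement with the Welch t interval: median endpoints over
  # 50 seeds within 10% of the t-based interval
  set.seed(67)
  a <- rnorm(50); b <- rnorm(50)
  tt <- stats::t.test(b, a)
  ends <- t(vapply(1:50, function(s) {
    e <- bca_ci(a, b, n_boot = 2000, seed = s)
    c(e$ci_low, e$ci_high)
  }, numeric(2)))
  t_width <- diff(as.numeric(tt$conf.int))
  expect_lt(abs(median(ends[, 1]) - tt$conf.int[1]), 0.1 * t_width)
  expect_lt(abs(median(ends[, 2]) - tt$conf.int[2]), 0.1 * t_width)
})

test_that("pairwise comparison reports carry Sidak adjustment and BCa intervals", {
  set.seed(77)
  tab <- data.frame(
    group = rep(c("IN(-,-)", "IN(+,-)", "IN(-,+)", "IN(+,+)"), each = 6),
    percent_engulfed = rnorm(24, rep(c(2, 2.5, 4, 4.5), each = 6), 0.5))
  cmp <- pairwise_comparisons(
    tab, "percent_engulfed",
    comparisons = list(c("IN(-,-)", "IN(+,-)"), c("IN(-,+)", "IN(+,+)")),
    n_boot = 500, seed = 5)
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$p_sidak >= cmp$p - 1e-15))
  expect_true(all(cmp$ci_low <= cmp$mean_difference &
                    cmp$mean_difference <= cmp$ci_high))
})
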