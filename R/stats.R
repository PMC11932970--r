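#' Two-way factorial ANOVA
#'
#' Fits the full factorial linear model `value ~ A * B` and returns the
#' four-row ANOVA table (factor A, factor B, interaction, residual). For
#' unbalanced data, Type III sums of squares with sum-to-zero contrasts are
#' used (matching the behaviour of the common graphing/statistics packages
#' this assay is usually analysed with); on balanced data all
#' sums-of-squares types coincide.
#'
#' @param values Numeric response, one observation per experimental unit
#'   (here: per animal).
#' @param factor_a,factor_b Crossed factors (coerced to factor).
#' @param factor_names Length-2 labels for the table rows.
#' @return A data.frame of class `anova_table` with columns `term`,
#'   `sum_sq`, `df`, `statistic` (F), `p_value`; attribute `cells` holds the
#'   cell counts.
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          factor_names = c("factor_a", "factor_b")) {
  values <- as.numeric(values)
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (length(values) != length(fa) || length(values) != length(fb)) {
    stop("values and factors must have equal length", call. = FALSE)
  }
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    stop("each factor needs at least two levels", call. = FALSE)
  }
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    stop("empty design cell: the interaction is not estimable", call. = FALSE)
  }
  if (max(cells) < 2) {
    stop("at least one cell must contain two or more observations", call. = FALSE)
  }
  res_df <- length(values) - nlevels(fa) * nlevels(fb)
  if (res_df < 2) stop("fewer than 2 residual degrees of freedom", call. = FALSE)
  if (stats::var(values) == 0) {
    # constant response: every effect is exactly null
    df <- c(nlevels(fa) - 1, nlevels(fb) - 1,
            (nlevels(fa) - 1) * (nlevels(fb) - 1), res_df)
    out <- data.frame(
      term = c(factor_names[1], factor_names[2],
               paste(factor_names, collapse = ":"), "Residuals"),
      sum_sq = c(0, 0, 0, 0), df = df,
      statistic = c(0, 0, 0, NA_real_), p_value = c(1, 1, 1, NA_real_),
      stringsAsFactors = FALSE)
    attr(out, "cells") <- cells
    attr(out, "ss_type") <- "III (sum-to-zero contrasts)"
    class(out) <- c("anova_table", class(out))
    return(out)
  }
  dat <- data.frame(y = values, fa = fa, fb = fb)
  fit <- stats::lm(y ~ fa * fb, data = dat,
                   contrasts = list(fa = "contr.sum", fb = "contr.sum"))
  at <- car::Anova(fit, type = 3)
  rows <- c("fa", "fb", "fa:fb", "Residuals")
  ss <- at[rows, "Sum Sq"]
  df <- at[rows, "Df"]
  ms_res <- ss[4] / df[4]
  f <- numeric(3); p <- numeric(3)
  for (i in 1:3) {
    if (ss[i] <= 0 || isTRUE(all.equal(ss[i], 0))) {
      f[i] <- 0; p[i] <- 1
    } else if (ms_res == 0) {
      f[i] <- Inf; p[i] <- 0
    } else {
      f[i] <- (ss[i] / df[i]) / ms_res
      p[i] <- stats::pf(f[i], df[i], df[4], lower.tail = FALSE)
    }
  }
  out <- data.frame(
    term = c(factor_names[1], factor_names[2],
             paste(factor_names, collapse = ":"), "Residuals"),
    sum_sq = ss, df = df,
    statistic = c(f, NA_real_), p_value = c(p, NA_real_),
    stringsAsFactors = FALSE)
  attr(out, "cells") <- cells
  attr(out, "ss_type") <- "III (sum-to-zero contrasts)"
  class(out) <- c("anova_table", class(out))
  out
}

#' One-way ANOVA
#'
#' Standard between/within decomposition across two or more groups.
#'
#' @param values Numeric response.
#' @param group Grouping factor, or a list of numeric vectors (then `values`
#'   is ignored).
#' @param factor_name Label for the between-groups row.
#' @return A data.frame of class `anova_table` (between, residual rows).
#' @export
one_way_anova <- function(values, group = NULL, factor_name = "group") {
  if (is.list(values) && is.null(group)) {
    group <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(group)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(g) == 0)) stop("a group has zero observations", call. = FALSE)
  res_df <- length(values) - nlevels(g)
  if (res_df < 2) stop("fewer than 2 residual degrees of freedom", call. = FALSE)
  if (stats::var(values) == 0) {
    out <- data.frame(term = c(factor_name, "Residuals"),
                      sum_sq = c(0, 0), df = c(nlevels(g) - 1, res_df),
                      statistic = c(0, NA_real_), p_value = c(1, NA_real_),
                      stringsAsFactors = FALSE)
    class(out) <- c("anova_table", class(out))
    return(out)
  }
  at <- stats::anova(stats::lm(values ~ g))
  ss <- at[["Sum Sq"]]; df <- at[["Df"]]
  ms_res <- ss[2] / df[2]
  if (ss[1] <= 0 || isTRUE(all.equal(ss[1], 0))) {
    f <- 0; p <- 1
  } else if (ms_res == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ss[1] / df[1]) / ms_res
    p <- stats::pf(f, df[1], df[2], lower.tail = FALSE)
  }
  out <- data.frame(term = c(factor_name, "Residuals"),
                    sum_sq = ss, df = df,
                    statistic = c(f, NA_real_), p_value = c(p, NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", class(out))
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("ANOVA table", if (!is.null(attr(x, "ss_type"))) {
    sprintf("(type %s)", attr(x, "ss_type"))
  } else "", "\n")
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. With exactly equal sample variances and equal n
#' the df reduce to `n_a + n_b - 2`.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A list with `t`, `df`, `p`, and the group means.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least two observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
    }
    stop("both samples are constant with unequal means: t is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(b, a, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons, clipped to
#' `[0, 1]`. Monotone in both `p` and `m`; never decreases a p-value for
#' `m >= 1`.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p_values)` and must be at least
#'   the number of comparisons.
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p)) {
    stop("family size m must be at least the number of comparisons", call. = FALSE)
  }
  clip01(1 - (1 - p)^m)
}

# Bootstrap quantiles by interpolation of order statistics on the normal
# quantile scale with the (B + 1) rank convention -- the standard endpoint
# rule for bootstrap confidence limits, slightly wider in the tails than
# plain empirical quantiles.
norm_inter <- function(x, probs) {
  b <- length(x)
  xs <- sort(x)
  vapply(probs, function(p) {
    r <- (b + 1) * p
    if (r <= 1) return(xs[1])
    if (r >= b) return(xs[b])
    k <- floor(r)
    g <- (stats::qnorm(p) - stats::qnorm(k / (b + 1))) /
      (stats::qnorm((k + 1) / (b + 1)) - stats::qnorm(k / (b + 1)))
    xs[k] + g * (xs[k + 1] - xs[k])
  }, numeric(1))
}

#' BCa bootstrap confidence interval for a two-group mean difference
#'
#' Estimation-statistics companion to the null-hypothesis tests: the point
#' estimate is `mean(group2) - mean(group1)`; groups are resampled
#' independently; the interval is the bias-corrected and accelerated (BCa)
#' percentile interval. The bias correction `z0` comes from the proportion
#' of bootstrap statistics below the point estimate; the acceleration `a`
#' from the jackknife skewness of the statistic, with leave-one-out carried
#' out within each group and pooled. Deterministic given `seed` (mandatory:
#' no hidden global RNG state).
#'
#' Degenerate inputs (both groups constant, or a collapsed bootstrap
#' distribution) yield a zero-width interval at the point estimate with
#' `degenerate = TRUE`.
#'
#' @param group1,group2 Numeric samples, each of length >= 2.
#' @param n_boot Number of bootstrap resamples (default 5000; >= 1000
#'   recommended for stable intervals).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (required).
#' @return A list of class `bootstrap_estimate`: `mean_difference`,
#'   `ci_low`, `ci_high`, `level`, `n_boot`, `seed`, `z0`, `acceleration`,
#'   `degenerate`.
#' @export
bca_ci <- function(group1, group2, n_boot = 5000, level = 0.95, seed) {
  g1 <- as.numeric(group1); g2 <- as.numeric(group2)
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least two observations", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("'seed' is required", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  est <- mean(g2) - mean(g1)
  mk <- function(ci_low, ci_high, z0 = NA_real_, a = NA_real_, degenerate = FALSE) {
    structure(list(mean_difference = est, ci_low = ci_low, ci_high = ci_high,
                   level = level, n_boot = as.integer(n_boot),
                   seed = as.integer(seed), z0 = z0, acceleration = a,
                   degenerate = degenerate),
              class = "bootstrap_estimate")
  }
  if (stats::var(g1) == 0 && stats::var(g2) == 0) {
    return(mk(est, est, degenerate = TRUE))
  }
  boot_stat <- with_seed(seed, {
    m1 <- colMeans(matrix(sample(g1, n1 * n_boot, replace = TRUE), n1))
    m2 <- colMeans(matrix(sample(g2, n2 * n_boot, replace = TRUE), n2))
    m2 - m1
  })
  if (max(boot_stat) == min(boot_stat)) {
    return(mk(boot_stat[1], boot_stat[1], degenerate = TRUE))
  }
  prop <- mean(boot_stat < est)
  degenerate <- FALSE
  if (prop <= 0 || prop >= 1) {
    prop <- min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
    degenerate <- TRUE
  }
  z0 <- stats::qnorm(prop)
  # jackknife acceleration: leave-one-out within each group, pooled
  loo1 <- (sum(g1) - g1) / (n1 - 1) # mean(g1[-i])
  loo2 <- (sum(g2) - g2) / (n2 - 1)
  theta <- c(mean(g2) - loo1, loo2 - mean(g1))
  d <- mean(theta) - theta
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  alpha <- (1 - level) / 2
  zlo <- stats::qnorm(alpha); zhi <- stats::qnorm(1 - alpha)
  adj <- function(zq) stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  qs <- norm_inter(boot_stat, c(adj(zlo), adj(zhi)))
  mk(qs[1], qs[2], z0 = z0, a = a, degenerate = degenerate)
}

#' @export
print.bootstrap_estimate <- function(x, ...) {
  cat(sprintf("mean difference %.4g [%g%% CI %.4g, %.4g] (BCa, %d resamples, seed %d)%s\n",
              x$mean_difference, 100 * x$level, x$ci_low, x$ci_high,
              x$n_boot, x$seed,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Pairwise group comparisons with Sidak adjustment and BCa estimates
#'
#' For each requested pair of groups, computes Welch's t (Sidak-adjusted over
#' the family of requested comparisons) and the BCa bootstrap estimate of the
#' mean difference. The comparison set is explicit configuration and is
#' never inferred from the data.
#'
#' @param table A data.frame (e.g. a `cohort_table`).
#' @param metric Name of the response column.
#' @param group_col Name of the group-label column (default `"group"`).
#' @param comparisons List of length-2 character vectors
#'   `c(group1, group2)`; the reported difference is group2 - group1.
#' @param n_boot,level Passed to [bca_ci()].
#' @param seed Master seed; each comparison uses a [split_seed()] stream.
#' @return A data.frame with one row per comparison: groups, n's, mean
#'   difference, `t`, `df`, `p`, `p_sidak`, `ci_low`, `ci_high`.
#' @export
pairwise_comparisons <- function(table, metric, comparisons,
                                 group_col = "group", n_boot = 5000,
                                 level = 0.95, seed = 1) {
  rows <- lapply(seq_along(comparisons), function(i) {
    cp <- comparisons[[i]]
    a <- table[[metric]][table[[group_col]] == cp[1]]
    b <- table[[metric]][table[[group_col]] == cp[2]]
    if (length(a) < 2 || length(b) < 2) {
      stop(sprintf("comparison %s vs %s has a group with < 2 animals",
                   cp[1], cp[2]), call. = FALSE)
    }
    wt <- welch_t(a, b)
    bca <- bca_ci(a, b, n_boot = n_boot, level = level,
                  seed = split_seed(seed, i))
    data.frame(group1 = cp[1], group2 = cp[2],
               n1 = length(a), n2 = length(b),
               mean_difference = bca$mean_difference,
               t = wt$t, df = wt$df, p = wt$p,
               ci_low = bca$ci_low, ci_high = bca$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_sidak <- sidak_adjust(out$p, m = length(comparisons))
  out
}
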