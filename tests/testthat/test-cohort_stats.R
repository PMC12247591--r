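test_that("welch_t matches the reference values and conventions", {
  r <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.224744871391589, tolerance = 1e-9)
  expect_equal(r$df, 4, tolerance = 1e-9)
  expect_equal(r$p, 0.2878641347266905, tolerance = 1e-9)
  expect_equal(r$effect_size, -1, tolerance = 1e-12)  # pooled-SD d

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(same$effect_size, 0)

  # large-sample d approaches the standardized mean difference
  set.seed(1)
  x <- rnorm(5000, 0, 1); y <- rnorm(5000, 1, 1)
  expect_lt(abs(welch_t(x, y)$effect_size + 1), 0.06)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("welch_t equals the pooled t-test when variances and n are equal", {
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)  # force equal variance
  w <- welch_t(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(w$statistic, unname(pooled$statistic), tolerance = 1e-9)
  expect_equal(w$df, unname(pooled$parameter), tolerance = 1e-9)
})

test_that("one-way ANOVA matches the hand-computed table", {
  r <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 27, tolerance = 1e-9)
  expect_equal(r$p, 0.001, tolerance = 1e-6)
  ident <- one_way_anova(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  # two groups: F = t^2 of the pooled t-test
  set.seed(3)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  f2 <- one_way_anova(list(x, y))
  t2 <- t.test(x, y, var.equal = TRUE)
  expect_equal(f2$statistic, unname(t2$statistic)^2, tolerance = 1e-9)
  expect_equal(f2$p, t2$p.value, tolerance = 1e-9)
  expect_error(one_way_anova(list(1, c(1, 2))), "n >= 2")
})

test_that("adjusted contrast reduces to the pooled t-test without usable
           covariates and absorbs a pure confound", {
  set.seed(4)
  g <- factor(rep(c("a", "b"), each = 20))
  y <- rnorm(40) + 0.8 * (g == "b")
  r <- adjusted_group_contrast(y, g, data.frame(cv = rep(1, 40)))
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(r$p, tt$p.value, tolerance = 1e-9)

  # metric driven entirely by age, groups balanced on age: group p near 1
  age <- rep(rnorm(20, 50, 5), 2)
  y2 <- 2 * age + rnorm(40, sd = 1e-6)
  r2 <- adjusted_group_contrast(y2, g, data.frame(age = age))
  expect_gt(r2$p, 0.5)
  expect_lt(abs(r2$estimate), 1e-4)
})

test_that("adjusted contrast recovers an injected group shift", {
  hits <- 0
  for (s in 1:60) {
    set.seed(s)
    n <- 200
    g <- factor(rep(c("a", "b"), each = n / 2))
    age <- rnorm(n, 50, 5)
    y <- 1 * (g == "b") + 0.05 * age + rnorm(n, sd = 1)
    est <- adjusted_group_contrast(y, g, data.frame(age = age))$estimate
    if (est > 0.8 && est < 1.2) hits <- hits + 1
  }
  expect_gte(hits, 54)  # >= 90%
})

test_that("trend test is antisymmetric and matches a permutation oracle", {
  g <- factor(rep(c("a", "b", "c"), each = 2), ordered = TRUE)
  r <- trend_test(c(1, 1, 2, 2, 3, 3), g)
  expect_gt(r$statistic, 0)
  expect_lt(r$p, 0.05)
  rev_r <- trend_test(c(1, 1, 2, 2, 3, 3),
                      factor(as.character(g), levels = c("c", "b", "a"),
                             ordered = TRUE))
  expect_equal(rev_r$statistic, -r$statistic, tolerance = 1e-12)

  # permutation oracle for the z-score's tail probability at tiny n
  set.seed(7)
  y <- c(0.3, 1.2, 0.8, 1.9, 2.4, 1.1, 3.0, 2.2, 2.8)
  gg <- factor(rep(c("a", "b", "c"), each = 3), ordered = TRUE)
  obs <- trend_test(y, gg)
  l <- as.numeric(gg); r_y <- rank(y)
  T_obs <- sum(l * r_y)
  perm <- replicate(20000, sum(l * sample(r_y)))
  p_perm <- mean(abs(perm - mean(perm)) >= abs(T_obs - mean(perm)) - 1e-9)
  expect_lt(abs(obs$p - p_perm), 0.03)

  # two ordered groups reduce to the Wilcoxon rank-sum normal approximation
  set.seed(8)
  x <- rnorm(15); y2 <- rnorm(15, 0.8)
  g2 <- factor(rep(c("a", "b"), each = 15), ordered = TRUE)
  tr2 <- trend_test(c(x, y2), g2)
  wil <- wilcox.test(y2, x, exact = FALSE, correct = FALSE)
  expect_equal(tr2$p, wil$p.value, tolerance = 1e-9)

  expect_error(trend_test(rep(1, 6), g), "tied")
  expect_error(trend_test(1:3, factor(rep("a", 3), ordered = TRUE)),
               "ordered groups")
})

test_that("adjusted Spearman reduces, saturates and partials out", {
  r <- adjusted_spearman(c(1, 2, 3), c(1, 4, 9))
  expect_equal(r$estimate, 1)
  expect_equal(r$p, 0)

  set.seed(9)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50)
  plain <- cor.test(x, y, method = "spearman", exact = FALSE)
  r2 <- adjusted_spearman(x, y, data.frame(cv = rep(2, 50)))
  expect_equal(r2$estimate, unname(plain$estimate), tolerance = 1e-9)

  # covariate-driven component is fully absorbed: adjusted rho near -1,
  # while the plain Spearman is masked by the covariate
  cv <- runif(400)
  x4 <- rnorm(400)
  y4 <- -x4 + 10 * cv
  r4 <- adjusted_spearman(x4, y4, data.frame(cv = cv))
  expect_lt(r4$estimate, -0.8)
  expect_lt(r4$estimate, cor(x4, y4, method = "spearman"))
  expect_error(adjusted_spearman(rep(1, 10), rnorm(10)), "constant")
})

test_that("BH step-up matches hand results and is order-invariant", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$rejected))
  expect_equal(r$p_adjusted, c(0.04, 0.04, 0.04, 0.04))
  r1 <- bh_fdr(0.04, alpha = 0.05)
  expect_true(r1$rejected)
  expect_equal(r1$p_adjusted, 0.04)

  set.seed(10)
  p <- runif(20)
  perm <- sample(20)
  a <- bh_fdr(p)$p_adjusted
  b <- bh_fdr(p[perm])$p_adjusted
  expect_equal(b, a[perm], tolerance = 1e-12)
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("standardized OLS recovers exact fits and rejects bad designs", {
  set.seed(11)
  x <- rnorm(30)
  r <- suppressWarnings(ols_standardized(2 * x + 3, data.frame(x = x)))
  expect_equal(r$estimate, 1, tolerance = 1e-9)
  expect_lt(r$p, 1e-12)
  expect_error(ols_standardized(rnorm(30), data.frame(a = x, b = x)),
               "rank-deficient")
  expect_error(ols_standardized(rnorm(30), data.frame(a = rep(1, 30))),
               "zero-variance")
})

test_that("distribution diagnostics match known shapes", {
  expect_equal(distribution_diagnostics(c(1, 2, 3))$skew, 0)
  set.seed(12)
  z <- rnorm(1e5)
  dz <- distribution_diagnostics(z)
  expect_lt(abs(dz$skew), 0.03)
  expect_lt(abs(dz$kurtosis_excess), 0.06)
  expect_equal(dz$kurtosis_pearson, dz$kurtosis_excess + 3)
  e <- rexp(1e5)
  expect_lt(abs(distribution_diagnostics(e)$skew - 2), 0.1)
  expect_error(distribution_diagnostics(rep(2, 10)), "constant")
})

test_that("outlier trimming removes exactly the top-k in the target group", {
  set.seed(13)
  dat <- data.frame(
    subject_id = sprintf("S%02d", 1:30),
    group = rep(c("exposed_noptsd", "ptsd"), each = 15),
    wcpl = c(rnorm(15, 50, 5), rnorm(15, 60, 10)))
  count_fn <- function(d) stat_result("count", n = nrow(d))
  s0 <- outlier_sensitivity(dat, "ptsd", k = 0, analysis = count_fn)
  expect_identical(s0$full, s0$trimmed)

  s3 <- outlier_sensitivity(dat, "ptsd", k = 3, analysis = count_fn,
                            threshold = 60)
  expect_equal(s3$trimmed$n, 27L)
  expect_length(s3$removed_ids, 3)
  in_ptsd <- dat$group == "ptsd"
  top3 <- dat$subject_id[in_ptsd][order(dat$wcpl[in_ptsd],
                                        decreasing = TRUE)][1:3]
  expect_setequal(s3$removed_ids, top3)
  # other group untouched; trimmed max bounded by the 4th order statistic
  trimmed_w <- dat$wcpl[!(dat$subject_id %in% s3$removed_ids) & in_ptsd]
  expect_lte(max(trimmed_w), sort(dat$wcpl[in_ptsd], decreasing = TRUE)[4])
  expect_equal(s3$n_above_threshold, sum(dat$wcpl > 60))
  expect_equal(s3$n_above_threshold_in_group,
               sum(dat$wcpl > 60 & in_ptsd))
  expect_error(outlier_sensitivity(dat, "ptsd", k = 15,
                                   analysis = count_fn), "smaller")
})
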