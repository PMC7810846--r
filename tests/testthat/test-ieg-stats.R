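test_that("densities come from frame means over the 0.1305 mm^2 frame", {
  tab <- data.frame(bird_id = "b1", group = "MATE", region = "CMM",
                    ieg = "Zenk", frame_index = 1:4, count = c(13, 13, 13, 13))
  d <- density_from_counts(tab)
  expect_equal(d$density_per_mm2, 13 / 0.1305)

  tab$count <- c(10, 12, 14, 16)
  expect_equal(density_from_counts(tab)$density_per_mm2, 13 / 0.1305)

  tab$count <- rep(0, 4)
  expect_equal(density_from_counts(tab)$density_per_mm2, 0)

  expect_warning(density_from_counts(tab[1:3, ]), "fewer than 4")
  tab$count[1] <- -1
  expect_error(density_from_counts(tab), "nonnegative")
})

test_that("log transform is monotone with 0 mapping to 0", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  expect_error(log_transform(-0.1), "negative")
  set.seed(30)
  x <- rexp(50, 0.01)
  expect_identical(order(log_transform(x)), order(x))
})

test_that("F upper tails reproduce the reference ANOVA p-values", {
  expect_equal(round(f_survival(9.197, 2, 9), 3), 0.007)
  expect_equal(round(f_survival(1.898, 2, 9), 3), 0.205)
  expect_equal(f_survival(0, 2, 9), 1)
  expect_error(f_survival(-1, 2, 9), "nonnegative")
  expect_error(f_survival(1, 0, 9), "freedom")
})

test_that("df1 = 2 closed form matches the beta-function route", {
  for (f in c(0, 0.3, 1, 2.5, 7.788, 9.197, 25)) {
    for (d2 in c(1, 4, 9, 36)) {
      expect_equal(f_survival(f, 2, d2), (d2 / (d2 + 2 * f))^(d2 / 2),
                   tolerance = 1e-10)
    }
  }
})

test_that("one-way ANOVA matches hand sums of squares and handles zero variance", {
  a <- one_way_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(1:3, each = 3))
  expect_equal(a$F, 3)            # SSB = 6 (df 2), SSW = 6 (df 6)
  expect_equal(c(a$df1, a$df2), c(2, 6))
  expect_equal(a$p, f_survival(3, 2, 6))

  z <- one_way_anova(rep(2, 9), rep(1:3, each = 3))
  expect_equal(z$F, 0)
  expect_equal(z$p, 1)
  expect_error(one_way_anova(1:3, 1:3), ">= 2 values")
})

test_that("one-way ANOVA rejection rate agrees with a permutation-F oracle", {
  set.seed(31)
  alpha <- 0.05
  n_sim <- 300
  rej_f <- rej_perm <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    y <- c(rnorm(4, 2.2, 0.25), rnorm(4, 2.0, 0.25), rnorm(4, 1.2, 0.25))
    g <- rep(1:3, each = 4)
    a <- one_way_anova(y, g)
    rej_f[i] <- a$p < alpha
    fstat <- function(yy) {
      m <- tapply(yy, g, mean); gm <- mean(yy)
      ssb <- 4 * sum((m - gm)^2)
      ssw <- sum((yy - m[g])^2)
      (ssb / 2) / (ssw / 9)
    }
    perm <- replicate(120, fstat(sample(y)))
    rej_perm[i] <- mean(perm >= a$F) < alpha
  }
  expect_lt(abs(mean(rej_f) - mean(rej_perm)), 0.05)
})

test_that("two-way ANOVA has the study's layout and matches a balanced-SS oracle", {
  set.seed(32)
  y <- rnorm(48)
  g <- rep(c("MATE", "UNFAMILIAR", "SILENCE"), each = 16)
  r <- rep(rep(c("CMM", "dNCM", "vNCM", "HP"), each = 4), 3)
  res <- two_way_anova(y, g, r)
  expect_equal(c(res$A$df1, res$B$df1, res$interaction$df1), c(2, 3, 6))
  expect_equal(res$interaction$df2, 36)

  y2 <- rnorm(12)
  a2 <- rep(c("x", "y"), each = 6)
  b2 <- rep(rep(c("u", "v"), each = 3), 2)
  res2 <- two_way_anova(y2, a2, b2)
  oracle <- balanced_two_way_ss(y2, a2, b2)
  expect_equal(res2$A$F, oracle$FA, tolerance = 1e-9)
  expect_equal(res2$B$F, oracle$FB, tolerance = 1e-9)
  expect_equal(res2$interaction$F, oracle$FAB, tolerance = 1e-9)

  # additive cell means leave no interaction (replicate noise is
  # symmetric within cells so the cell means stay exactly additive)
  add <- as.numeric(outer(c(1, 2), c(0, 3, 5), "+"))
  y3 <- rep(add, each = 2) + rep(c(-0.5, 0.5), 6)
  a3 <- rep(rep(c("x", "y"), 3), each = 2)
  b3 <- rep(c("u", "v", "w"), each = 4)
  expect_equal(two_way_anova(y3, a3, b3)$interaction$F, 0, tolerance = 1e-9)

  expect_error(two_way_anova(y2[-1], a2[-1], b2[-1]), "unbalanced")
})

test_that("Bonferroni post-hocs use the pooled error and cap at 1", {
  set.seed(33)
  y <- c(rnorm(4), rnorm(4), rnorm(4) + 5)
  g <- rep(c("a", "b", "c"), each = 4)
  ph <- bonferroni_posthoc(y, g)
  expect_equal(ph$p_adjusted, pmin(1, 3 * ph$p_raw))
  expect_true(all(ph$p_adjusted[ph$group2 == "c" | ph$group1 == "c"] < 0.05))
  expect_gt(ph$p_adjusted[ph$group1 == "a" & ph$group2 == "b"], 0.05)

  # cross-check raw p against pairwise.t.test with pooled SD
  pw <- pairwise.t.test(y, g, p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(ph$p_raw[1], pw$p.value["b", "a"], tolerance = 1e-12)
  expect_equal(ph$p_raw[2], pw$p.value["c", "a"], tolerance = 1e-12)

  same <- bonferroni_posthoc(rep(c(1, 2), 6), rep(c("a", "b", "c"), each = 4))
  expect_error(bonferroni_posthoc(y, g, pairs = list(c("a", "zz"))),
               "unknown group")
})

test_that("Pearson correlation matches cor.test and the n = 4 identity", {
  set.seed(34)
  x <- rnorm(10); y <- rnorm(10)
  r <- pearson_corr(x, y)
  ct <- cor.test(x, y)
  expect_equal(r$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p, ct$p.value, tolerance = 1e-12)

  exact <- pearson_corr(1:4, 1:4)
  expect_equal(exact$r, 1)
  expect_equal(exact$p, 0)

  const <- pearson_corr(rep(1, 4), rnorm(4))
  expect_true(const$undefined)
  expect_true(is.na(const$r) && is.na(const$p))
  expect_error(pearson_corr(1:2, 1:2), "n >= 3")
})

test_that("at n = 4 the two-tailed p equals 1 - |r| across the whole range", {
  for (r_target in seq(-0.999, 0.999, length.out = 1000)) {
    x <- c(-3, -1, 1, 3)
    e <- c(1, -1, -1, 1)  # orthogonal to x, mean zero
    y <- r_target * x / sqrt(sum(x^2)) +
      sqrt(1 - r_target^2) * e / sqrt(sum(e^2))
    res <- pearson_corr(x, y)
    expect_equal(res$r, r_target, tolerance = 1e-9)
    expect_equal(res$p, 1 - abs(r_target), tolerance = 1e-12)
  }
})

test_that("region correlation matrix covers the three pairs and validates input", {
  dens <- data.frame(
    bird_id = rep(sprintf("b%d", 1:4), 3),
    region = rep(c("CMM", "dNCM", "vNCM"), each = 4),
    density_per_mm2 = rep(c(100, 200, 300, 400), 3))
  out <- region_correlation_matrix(dens)
  expect_named(out, c("CMM-dNCM", "CMM-vNCM", "dNCM-vNCM"))
  expect_true(all(vapply(out, function(cr) cr$r, 1) == 1))

  expect_error(region_correlation_matrix(dens[-1, ]), "missing a region")
})

test_that("reference-prior credible intervals equal classical OLS intervals", {
  set.seed(35)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    x <- rnorm(n)
    y <- 1 + 0.5 * x + rnorm(n)
    fit <- bayes_simple_regression(x, y)
    lm_ci <- confint(lm(y ~ x))["x", ]
    expect_equal(fit$ci_lo, unname(lm_ci[1]), tolerance = 1e-9)
    expect_equal(fit$ci_hi, unname(lm_ci[2]), tolerance = 1e-9)
    expect_equal(fit$slope_mean, unname(coef(lm(y ~ x))["x"]),
                 tolerance = 1e-9)
    expect_identical(fit$includes_zero, fit$ci_lo <= 0 && 0 <= fit$ci_hi)
  }
})

test_that("a strong slope excludes zero; weak n = 4 correlation includes it", {
  set.seed(36)
  x <- rnorm(50)
  y <- 2 * x + rnorm(50, 0, 0.01)
  fit <- bayes_simple_regression(x, y)
  expect_true(fit$slope_mean > 1.99 && fit$slope_mean < 2.01)
  expect_false(fit$includes_zero)

  # sample correlation 0.753 at n = 4 has p = 0.247: CI spans zero
  x4 <- c(-3, -1, 1, 3)
  e4 <- c(1, -1, -1, 1)
  y4 <- 0.753 * x4 / sqrt(sum(x4^2)) + sqrt(1 - 0.753^2) * e4 / sqrt(sum(e4^2))
  fit4 <- bayes_simple_regression(x4, y4)
  expect_true(fit4$includes_zero)

  expect_error(bayes_simple_regression(rep(1, 5), rnorm(5)), "constant")
})

test_that("the shrinkage prior pulls the slope toward zero", {
  set.seed(37)
  x <- rnorm(8)
  y <- 1.5 * x + rnorm(8, 0, 0.3)
  ref <- bayes_simple_regression(x, y)
  shrunk <- bayes_simple_regression(x, y, prior = "normal", tau2 = 0.01)
  expect_lt(abs(shrunk$slope_mean), abs(ref$slope_mean))
  loose <- bayes_simple_regression(x, y, prior = "normal", tau2 = 1e6)
  expect_equal(loose$slope_mean, ref$slope_mean, tolerance = 1e-3)
})

test_that("pattern profiles scale, rank, and measure concordance correctly", {
  dens <- data.frame(
    bird_id = rep(sprintf("b%d", 1:4), 3),
    region = rep(c("CMM", "dNCM", "vNCM"), each = 4),
    density_per_mm2 = c(10, 20, 30, 40, 1, 2, 3, 4, 5, 10, 15, 20))
  p <- pattern_profiles(dens)
  expect_true(all(apply(p$scaled_percent, 2, max) == 100))
  expect_true(p$concordant)
  expect_equal(p$kendalls_w, 1)

  # reverse one region's ordering: rank sums (6,7,8,9), S = 5,
  # W = 12*5 / (9 * 60) = 1/9
  dens$density_per_mm2[9:12] <- c(20, 15, 10, 5)
  p2 <- pattern_profiles(dens)
  expect_false(p2$concordant)
  expect_equal(p2$kendalls_w, 1 / 9)
})

test_that("Spearman rank correlation is exact for small n and flags constants", {
  r <- spearman_score_vs_counts(c(1, 2, 3, 4), c(10, 20, 40, 30))
  expect_equal(r$rho, 0.8)  # 1 - 6*2/60

  mono <- spearman_score_vs_counts(1:5, c(2, 4, 8, 16, 32))
  expect_equal(mono$rho, 1)

  # exact permutation p agrees with cor.test's exact method when tie-free
  set.seed(38)
  x <- sample(1:7); y <- sample(1:7)
  ours <- spearman_score_vs_counts(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(ours$p, ct$p.value, tolerance = 1e-12)

  const <- spearman_score_vs_counts(rep(2, 4), rnorm(4))
  expect_true(const$undefined)
})

test_that("ANOVA decomposition is exact on random data", {
  set.seed(39)
  for (i in 1:10) {
    y <- rnorm(30)
    g <- factor(sample(1:3, 30, replace = TRUE, prob = c(1, 1, 1)))
    while (any(table(g) < 2)) g <- factor(sample(1:3, 30, replace = TRUE))
    ssb <- sum(tapply(y, g, length) * (tapply(y, g, mean) - mean(y))^2)
    ssw <- sum((y - ave(y, g))^2)
    expect_equal(ssb + ssw, sum((y - mean(y))^2), tolerance = 1e-9)
    a <- one_way_anova(y, g)
    expect_equal(a$F, (ssb / a$df1) / (ssw / a$df2), tolerance = 1e-9)
  }
})
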