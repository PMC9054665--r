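test_that("permutation test returns p = 1 when the group sits at the background mean", {
  bg <- rep(2, 50)
  pt <- permutation_test(rep(2, 8), bg, n_perm = 199, seed = 1)
  expect_equal(pt$observed, 0)
  expect_equal(pt$p_value, 1)
})

test_that("permutation p agrees with exhaustive subset enumeration", {
  # small backgrounds: every subset enumerable, exact two-sided p computable
  cases <- list(list(bg = c(1, 1, 2), g = 1),
                list(bg = c(0, 1, 1, 2, 3, 5, 1, 0, 2, 4, 1, 1), g = 3),
                list(bg = c(2, 2, 0, 1, 7, 3, 1, 0, 5, 2), g = 4))
  for (cs in cases) {
    bg <- cs$bg
    grp <- bg[seq_len(cs$g)]  # group drawn from the background itself
    obs <- mean(grp) - mean(bg)
    subs <- combn(length(bg), cs$g)
    tstar <- apply(subs, 2, function(ix) mean(bg[ix]) - mean(bg))
    exact <- mean(abs(tstar) >= abs(obs) - 1e-12)
    pt <- permutation_test(grp, bg, n_perm = 9999, seed = 5)
    # Monte-Carlo standard error of the exact proportion
    se <- sqrt(exact * (1 - exact) / 9999)
    expect_lt(abs(pt$p_value - exact), 4 * se + 2 / 9999)
  }
})

test_that("permutation test is bit-reproducible under a fixed seed", {
  withr::local_seed(99)
  bg <- rpois(200, 1.5) + 1
  grp <- sample(bg, 20)
  a <- permutation_test(grp, bg, n_perm = 999, seed = 123)
  b <- permutation_test(grp, bg, n_perm = 999, seed = 123)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$observed, b$observed)
  c2 <- permutation_test(grp, bg, n_perm = 999, seed = 124)
  expect_false(identical(b$p_value, c2$p_value))
})

test_that("permutation test detects a planted mean shift", {
  withr::local_seed(7)
  bg <- rpois(2000, 1.5) + 1
  grp <- rpois(60, 3.5) + 1  # +2 occurrences on average
  pt <- permutation_test(grp, bg, n_perm = 9999, seed = 11)
  expect_lt(pt$p_value, 0.01)
  expect_gt(pt$observed, 0)
})

test_that("permutation p is super-uniform under the null", {
  withr::local_seed(31)
  bg <- rpois(300, 1.2) + 1
  ps <- vapply(1:300, function(i) {
    grp <- bg[sample.int(300, 15)]
    permutation_test(grp, bg, n_perm = 199, seed = 1000 + i)$p_value
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 300))
  }
  expect_gte(min(ps), 1 / 200)
})

test_that("permutation test input validation", {
  expect_error(permutation_test(numeric(0), 1:10, seed = 1), "non-empty")
  expect_error(permutation_test(1:11, 1:10, seed = 1), "larger than")
  expect_error(permutation_test(1:2, 1:10, n_perm = 0, seed = 1), "n_perm")
})

test_that("welch_t matches the closed-form statistic and is antisymmetric", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  wt <- welch_t(a, b)
  # direct evaluation of the Welch formulas
  se2 <- var(a) / 4 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(wt$t, t_hand, tolerance = 1e-12)
  expect_equal(wt$df, df_hand, tolerance = 1e-12)
  expect_equal(wt$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  rev <- welch_t(b, a)
  expect_equal(rev$t, -wt$t, tolerance = 1e-12)
  expect_equal(rev$p_value, wt$p_value, tolerance = 1e-12)

  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # equal variance, equal n: df reduces to the classical 2n - 2
  withr::local_seed(2)
  x <- rnorm(30); y <- x + 1  # identical spread
  expect_equal(welch_t(x, y)$df, 58, tolerance = 1e-9)

  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA reduces to t^2 for two groups and matches manual sums of squares", {
  g1 <- c(1, 2, 3); g2 <- c(2, 3, 4)
  res <- anova_oneway(list(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)

  # identical constant-shifted copies with zero between-group variance
  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)

  groups <- list(c(1, 2, 3, 4), c(3, 4, 5), c(0, 1, 1, 2, 1))
  res3 <- anova_oneway(groups)
  vals <- unlist(groups)
  gm <- mean(vals)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  F_hand <- (ssb / 2) / (ssw / (length(vals) - 3))
  expect_equal(res3$F, F_hand, tolerance = 1e-12)

  expect_error(anova_oneway(list(c(1, 2))), "at least 2")
  expect_error(anova_oneway(list(c(1, 1), c(1, 1))), "identical")
})
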