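test_that("log transform, geometric means, and fold range", {
  tab <- data.frame(clade = c("a", "b", "c"),
                    rate_myr = c(0.01, 0.1, 1),
                    group = c("g1", "g1", "g2"))
  lt <- log_rates(tab)
  expect_equal(lt$log10_rate, c(-2, -1, 0))
  expect_equal(unname(geometric_mean_rates(tab)["g1"]), 10^(-1.5))

  one <- data.frame(clade = "a", rate_myr = 0.023, group = "g")
  expect_equal(unname(geometric_mean_rates(one)), 0.023)

  expect_equal(fold_range(c(0.1, 0.1)), 1)
  expect_equal(fold_range(c(0.001, 0.5)), 500)
  expect_equal(fold_range(c(0.0008, 0.2, 0.7)), 875)
  expect_equal(log10(c(0.0008, 0.7)), c(-3.09691, -0.154902),
               tolerance = 1e-5)

  bad <- data.frame(clade = c("a", "b"), rate_myr = c(0.1, -1))
  expect_error(log_rates(bad), "non-positive rate.*b")
  expect_error(fold_range(0.1), ">= 2")
})

test_that("one-way ANOVA matches the hand-computed F and handles degeneracy", {
  # groups (1,2,3) vs (4,5,6): MSB = 13.5, MSW = 1, F = 13.5 on (1, 4)
  a <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("x", "y"), each = 3))
  expect_equal(a$F, 13.5)
  expect_equal(unname(a$df), c(1, 4))
  expect_equal(a$p_anova, pf(13.5, 1, 4, lower.tail = FALSE))

  expect_warning(
    d <- anova_oneway(c(1, 1, 5, 5), c("x", "x", "y", "y")),
    "zero within-group")
  expect_equal(d$F, Inf)

  expect_error(anova_oneway(1:5, rep("x", 5)), ">= 2 groups")

  # F agrees with the direct sum-of-squares computation
  # (and SSB + SSW = SST by construction of that computation)
  set.seed(2)
  v <- rnorm(30); g <- sample(letters[1:3], 30, replace = TRUE)
  a2 <- anova_oneway(v, g)
  ssw <- sum((v - ave(v, g))^2)
  sst <- sum((v - mean(v))^2)
  ssb <- sst - ssw
  G <- length(unique(g))
  expect_equal(a2$F, (ssb / (G - 1)) / (ssw / (30 - G)), tolerance = 1e-9)
})

test_that("REML variance components recover null, separated, and balanced cases", {
  # one common normal: ICC near 0
  set.seed(3)
  v <- rnorm(54)
  g <- rep(letters[1:3], each = 18)
  r <- reml_variance_components(v, g)
  expect_lt(r$icc, 0.15)
  expect_equal(r$pct_between, 100 * r$icc)

  # strongly separated means: ICC near 1
  set.seed(4)
  v2 <- rnorm(30, rep(c(0, 10, 20), each = 10), 0.1)
  expect_gt(reml_variance_components(v2, rep(1:3, each = 10))$icc, 0.99)

  # balanced case: REML equals the closed-form ANOVA estimator when MSB > MSW
  set.seed(5)
  n0 <- 8
  v3 <- rnorm(40, rep(rnorm(5, 0, 2), each = n0), 1)
  g3 <- rep(1:5, each = n0)
  a <- anova_oneway(v3, g3)
  msb <- a$F * sum((v3 - ave(v3, g3))^2) / a$df[2]
  msw <- sum((v3 - ave(v3, g3))^2) / a$df[2]
  r3 <- reml_variance_components(v3, g3)
  expect_equal(r3$sigma2_between, unname((msb - msw) / n0), tolerance = 1e-6)
  expect_equal(r3$sigma2_within, unname(msw), tolerance = 1e-6)
})

test_that("permutation p-values: floor, invariance, and error cases", {
  # observed F far above anything attainable by permutation
  v <- c(rnorm(15, 0, 0.01), rnorm(15, 100, 0.01))
  g <- rep(c("x", "y"), each = 15)
  p <- permutation_test(v, g, "F", n_perm = 9999, seed = 1)
  expect_equal(p$p_perm, 1 / 10000)

  expect_error(permutation_test(v, rep("x", 30), "F"), "usage error")
  expect_error(permutation_test(v, g, "F", n_perm = 50), ">= 99")

  # the fast-path observed statistic equals the ANOVA F
  set.seed(6)
  v2 <- rnorm(40); g2 <- sample(c("x", "y", "z"), 40, replace = TRUE)
  p2 <- permutation_test(v2, g2, "F", n_perm = 99, seed = 2)
  expect_equal(p2$stat_obs, anova_oneway(v2, g2)$F, tolerance = 1e-9)

  # ICC statistic path agrees qualitatively on separated data
  p3 <- permutation_test(v, g, "icc", n_perm = 99, seed = 3)
  expect_equal(p3$p_perm, 1 / 100)
})

test_that("PGLS equals OLS on a star phylogeny and flags singular designs", {
  star <- ape::stree(20, type = "star")
  star$edge.length <- rep(1, 20)
  set.seed(7)
  x <- rnorm(20); y <- 2 * x + rnorm(20)
  names(x) <- names(y) <- star$tip.label
  fit <- pgls(y, x, star)
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(fit$slope, ols["x", "Estimate"], tolerance = 1e-10)
  expect_equal(fit$slope_se, ols["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(fit$p_slope, ols["x", "Pr(>|t|)"], tolerance = 1e-10)

  expect_error(pgls(y, setNames(rep(1, 20), names(x)), star), "singular design")
})

test_that("PGLS p-values are calibrated under the Brownian null", {
  tr <- simulate_yule_tree(40, seed = 8)
  ps <- vapply(1:200, function(s) {
    x <- simulate_brownian(tr, 1, seed = 2 * s)
    y <- simulate_brownian(tr, 1, seed = 2 * s + 1)
    pgls(y, x, tr)$p_slope
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})
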