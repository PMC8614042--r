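test_that("Spearman correlation handles perfect, inverse and tied-rank cases", {
  expect_equal(spearman_correlation(1:3 * 1, c(1, 2, 3))$estimate, 1)
  expect_equal(spearman_correlation(c(1, 2, 3), c(3, 2, 1))$estimate, -1)
  r <- spearman_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$estimate, 0.8)
  expect_equal(r$n, 4)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("Spearman is rank-based and monotone-transform invariant", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    r0 <- spearman_correlation(x, y)$estimate
    expect_equal(spearman_correlation(rank(x), rank(y))$estimate, r0)
    expect_equal(spearman_correlation(exp(3 * x), y^3 + 10 * y)$estimate, r0)
  }
})

test_that("partial Spearman reduces to the marginal when the control is rank-orthogonal", {
  x <- 1:5
  y <- c(2, 4, 6, 8, 10)           # same ranks as x
  z <- c(2, 5, 3, 1, 4)            # zero rank correlation with x (and y)
  expect_equal(cor(x, z, method = "spearman"), 0)
  expect_equal(partial_spearman(x, y, z)$estimate, 1)
  expect_error(partial_spearman(x, y, x), "degenerate")
})

test_that("partial Spearman agrees with the rank-residual oracle on simulated triples", {
  set.seed(10)
  n <- 2000
  z <- rnorm(n)
  x <- 0.7 * z + rnorm(n)
  y <- 0.5 * z + 0.3 * x + rnorm(n)
  ours <- partial_spearman(x, y, z)$estimate
  # oracle: Spearman correlation of residuals from rank-on-rank OLS
  rx <- resid(lm(rank(x) ~ rank(z)))
  ry <- resid(lm(rank(y) ~ rank(z)))
  oracle <- cor(rx, ry, method = "spearman")
  expect_lt(abs(ours - oracle), 0.02)
  expect_lt(ours, cor(x, y, method = "spearman"))  # control removes shared z
})

test_that("linear regression reports slope, p and adjusted R-squared", {
  x <- 1:10
  fit <- suppressWarnings(linear_regression(x, 2 * x + 1))
  expect_equal(fit$estimate, 2)
  expect_equal(fit$adj_r2, 1)

  # n = 3 closed form
  x3 <- c(0, 1, 3); y3 <- c(1, 2, 2)
  f3 <- linear_regression(x3, y3)
  b <- cov(x3, y3) / var(x3)
  r2 <- cor(x3, y3)^2
  expect_equal(f3$estimate, b)
  expect_equal(f3$adj_r2, 1 - (1 - r2) * 2 / 1)

  set.seed(2)
  noise <- linear_regression(rnorm(10000), rnorm(10000))
  expect_lt(abs(noise$adj_r2), 0.01)
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("PGLS at lambda 0 reproduces OLS and star trees make lambda irrelevant", {
  set.seed(14)
  tr <- ape::rphylo(20, 1, 0)      # ultrametric
  d <- data.frame(species = tr$tip.label, x = rnorm(20), y = rnorm(20))
  f0 <- pgls_fit(y ~ x, d, tr, lambda = 0)
  ols <- lm(y ~ x, d)
  expect_lt(max(abs(coef(f0) - coef(ols))), 1e-8)
  expect_lt(abs(f0$p_value[2] - summary(ols)$coefficients[2, 4]), 1e-8)
  expect_lt(abs(f0$adj_r2 - summary(ols)$adj.r.squared), 1e-8)

  star <- ape::stree(20, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  d$species <- star$tip.label
  fs <- pgls_fit(y ~ x, d, star, lambda = 1)
  expect_lt(max(abs(coef(fs) - coef(lm(y ~ x, d)))), 1e-8)

  bad <- d; bad$species[1] <- "not_a_tip"
  expect_error(pgls_fit(y ~ x, bad, tr), "not_a_tip")
})

test_that("PGLS maximum likelihood lambda matches the GLS reference implementation", {
  skip_if_not_installed("nlme")
  for (s in 1:5) {
    set.seed(s)
    tr <- ape::rphylo(40, 1, 0)
    d <- data.frame(species = tr$tip.label, x = rnorm(40))
    # strong phylogenetic signal keeps the ML lambda in the interior,
    # where the unbounded reference optimiser is comparable
    d$y <- simulate_traits_on_tree(tr, 2, 0.9) + 0.4 * d$x
    ours <- pgls_fit(y ~ x, d, tr)
    ref <- nlme::gls(y ~ x, data = d,
                     correlation = ape::corPagel(0.5, tr, form = ~species),
                     method = "ML")
    expect_lt(abs(ours$lambda - coef(ref$modelStruct$corStruct)), 1e-3)
    expect_lt(max(abs(ours$coefficients - coef(ref))), 1e-5)
  }
})

test_that("Wilcoxon W follows the Mann-Whitney convention and its complement identity", {
  expect_equal(wilcoxon_w(c(1, 2), c(3, 4))$W, 0)
  expect_equal(wilcoxon_w(c(3, 4), c(1, 2))$W, 4)
  expect_equal(wilcoxon_w(c(1, 2, 3), c(1, 2, 3))$W, 4.5)  # n^2/2 with ties
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(11)
    wa <- wilcoxon_w(a, b)$W
    wb <- wilcoxon_w(b, a)$W
    expect_equal(wa + wb, 77)
    expect_gte(wa, 0); expect_lte(wa, 77)
  }
})

test_that("the pathway chi-square vanishes for proportional tables and matches the hand formula", {
  same <- chisq_pathway_counts(c(10, 20), c(100, 200))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  tab <- rbind(c(10, 30), c(90, 70))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - E)^2 / E)
  got <- chisq_pathway_counts(c(10, 30), c(100, 100))
  expect_equal(got$chi2, hand)
  expect_equal(got$df, 1)

  five <- chisq_pathway_counts(rep(10, 5), rep(100, 5))
  expect_equal(five$chi2, 0)
  expect_equal(five$df, 4)
})

test_that("the CTN difference is the scaled absolute difference, symmetric in its arguments", {
  expect_equal(ctn_difference(59, 59), 0)
  expect_equal(ctn_difference(50, 216), 166 / 216)
  set.seed(7)
  a <- sample(1:300, 20); b <- sample(1:300, 20)
  expect_equal(ctn_difference(a, b), ctn_difference(b, a))
  expect_true(all(ctn_difference(a, b) >= 0 & ctn_difference(a, b) <= 1))
  expect_error(ctn_difference(0, 5), "positive")
})

test_that("the quantile transform is the fractional average rank", {
  expect_equal(quantile_transform(c(10, 20, 30, 40)),
               c(0.25, 0.5, 0.75, 1))
  n <- 8
  expect_equal(quantile_transform(rep(3, n)), rep((n + 1) / (2 * n), n))
  set.seed(1)
  v <- rnorm(50)
  q <- quantile_transform(v)
  expect_equal(order(q), order(v))
  expect_true(all(q > 0 & q <= 1))
})

test_that("KO filtering applies both strict cutoffs and skips missing results", {
  kr <- data.frame(ko = c("K1", "K2", "K3", "K4"),
                   rho = c(0.5, 0.4, 0.9, NA),
                   pgls_p = c(0.01, 0.01, 0.2, 0.01))
  expect_warning(kept <- filter_significant_kos(kr), "skipped")
  expect_equal(kept, "K1")
})
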