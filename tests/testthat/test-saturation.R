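test_that("expression binning forms equal bins, drops the remainder, and is deterministic under ties", {
  r <- rec_table(expression = seq_len(1234) + 2, is_multi_exon = TRUE,
                 n_clusters = rep(c(0L, 1L), length.out = 1234))
  s <- bin_genes_by_expression(r, 500)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_genes, c(500, 500))

  r2 <- rec_table(expression = rep(10, 300), is_multi_exon = TRUE,
                  n_clusters = rep(c(0L, 1L, 1L), 100))
  s1 <- bin_genes_by_expression(r2, 100)
  s2 <- bin_genes_by_expression(r2[rev(seq_len(300)), ], 100)
  expect_equal(s1$asp, s2$asp)  # gene_id tie-break

  r3 <- rec_table(expression = seq_len(1000) + 2, is_multi_exon = TRUE,
                  n_clusters = 1L)
  expect_equal(nrow(bin_genes_by_expression(r3, 100)), 10)
  expect_error(bin_genes_by_expression(r3, 600), "fewer than 2")
})

test_that("bins are ordered by expression and per-bin ASP uses the bin's genes", {
  set.seed(3)
  expr <- 3 + rexp(600, 1 / 50)
  spliced <- as.integer(runif(600) < 0.5)
  r <- rec_table(expression = expr, is_multi_exon = TRUE,
                 n_clusters = spliced)
  s <- bin_genes_by_expression(r, 100)
  expect_true(all(diff(s$mean_expression) > 0))
  o <- order(expr, r$gene_id)
  expect_equal(s$asp[1], mean(spliced[o][1:100]))
  expect_equal(s$asl[6], mean(r$entropy_asl[o][501:600]))
})

test_that("the logistic fit recovers noiseless parameters and handles flat data", {
  x <- 1:12
  y <- 0.8 / (1 + exp((5 - x) / 2))
  f <- fit_saturation_curve(fake_series(y), "asp")
  expect_true(f$converged)
  expect_lt(abs(f$alpha - 0.8), 1e-6)
  expect_lt(abs(f$xmid - 5), 1e-5)
  expect_lt(abs(f$scal - 2), 1e-5)
  expect_true(all(diff(f$fitted_values) >= 0))
  expect_equal(unname(coef(f)["alpha"]), f$alpha)
  expect_equal(predict(f, 5), f$alpha / 2, tolerance = 1e-5)

  flat <- fit_saturation_curve(fake_series(rep(0.7, 10)), "asp")
  expect_equal(flat$alpha, 0.7)
  expect_equal(diff(range(flat$fitted_values)), 0)
})

test_that("alpha is recovered without material bias under binomial bin noise", {
  x <- 1:12
  truth <- 0.8 / (1 + exp((5 - x) / 2))
  set.seed(99)
  alphas <- replicate(30, {
    y <- rbinom(12, 500, truth) / 500
    fit_saturation_curve(fake_series(y), "asp")$alpha
  })
  expect_lt(abs(mean(alphas) - 0.8), 0.02)
})

test_that("plateau bins follow the successive-difference rule and the 4-bin saturation call", {
  mk_fit <- function(fitted, observed = fitted) {
    structure(list(alpha = max(fitted), xmid = 0, scal = 1, converged = TRUE,
                   fitted_values = fitted, x = seq_along(fitted),
                   observed = observed, response = "asp",
                   x_scale = "index"), class = "saturation_fit")
  }
  # all fitted equal: every bin is plateau, mean of observations
  obs <- c(0.5, 0.6, 0.7, 0.65, 0.55)
  pe <- plateau_estimate(mk_fit(rep(0.6, 5), obs))
  expect_equal(pe$n_plateau_bins, 5)
  expect_equal(pe$plateau_mean, mean(obs))
  expect_true(pe$saturated)

  # four successive differences below tol -> 4 plateau bins -> saturated
  f4 <- c(0.2, 0.4, 0.7, 0.7, 0.7, 0.7, 0.7)
  pe4 <- plateau_estimate(mk_fit(f4))
  expect_equal(pe4$n_plateau_bins, 4)
  expect_true(pe4$saturated)

  # one fewer -> not saturated
  f3 <- c(0.2, 0.4, 0.7, 0.7, 0.7, 0.7)
  pe3 <- plateau_estimate(mk_fit(f3))
  expect_equal(pe3$n_plateau_bins, 3)
  expect_false(pe3$saturated)

  # steep everywhere: no plateau, undefined mean
  pe0 <- plateau_estimate(mk_fit(c(0.1, 0.3, 0.5, 0.7)))
  expect_equal(pe0$n_plateau_bins, 0)
  expect_true(is.na(pe0$plateau_mean))
  expect_false(pe0$saturated)

  # plateau mean lies within the observed plateau range
  obs2 <- c(0.2, 0.4, 0.66, 0.72, 0.69, 0.71)
  pe2 <- plateau_estimate(mk_fit(c(0.2, 0.4, 0.7, 0.7, 0.7, 0.7), obs2))
  expect_gte(pe2$plateau_mean, min(obs2[4:6]))
  expect_lte(pe2$plateau_mean, max(obs2[4:6]))
})

test_that("a decreasing tail moves the plateau mean less than its size and barely moves alpha", {
  x <- 1:14
  clean <- 0.8 / (1 + exp(4 - x))
  dip <- 0.05
  tailed <- clean
  tailed[13:14] <- tailed[13:14] - dip

  f_clean <- fit_saturation_curve(fake_series(clean), "asp")
  f_tail <- fit_saturation_curve(fake_series(tailed), "asp")
  expect_lt(abs(f_tail$alpha - f_clean$alpha), dip)

  p_clean <- plateau_estimate(f_clean, tol = 1e-3)
  p_tail <- plateau_estimate(f_tail, tol = 1e-3)
  expect_lt(abs(p_tail$plateau_mean - p_clean$plateau_mean), dip)
})

test_that("thinning junction reads does not systematically inflate the depth-corrected ASP", {
  n_seeds <- 8
  full_est <- thin_est <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    b <- simulate_species_set(sim_config(n_species = 2, n_genes = 900),
                              seed = 500 + i)
    s <- b$species[[1]]
    run <- function(j) {
      cl <- assign_and_filter_clusters(cluster_junctions(j), s$annotation)
      rec <- gene_splicing_records(s$annotation, cl, coverage = s$coverage)
      e <- estimate_splicing_saturation(rec, 60, "asp")
      if (!is.na(e$plateau$plateau_mean)) e$plateau$plateau_mean
      else max(e$fit$observed)
    }
    full_est[i] <- run(s$junctions)
    thin_est[i] <- run(thin_counts(s$junctions, 0.4, seed = i))
  }
  # one-sided sign test: increases under thinning must not dominate
  n_up <- sum(thin_est > full_est)
  p <- stats::binom.test(n_up, n_seeds, 0.5,
                         alternative = "greater")$p.value
  expect_gt(p, 0.05)
})

test_that("the bin-size robustness scan reports per-species and correlation SDs", {
  set.seed(12)
  b <- simulate_species_set(sim_config(n_species = 3, n_genes = 700),
                            seed = 61)
  recs <- lapply(b$species, function(s) {
    cl <- assign_and_filter_clusters(cluster_junctions(s$junctions),
                                     s$annotation)
    gene_splicing_records(s$annotation, cl, coverage = s$coverage)
  })
  trait <- stats::setNames(b$traits$ctn, b$traits$species)
  rb <- suppressWarnings(
    binsize_robustness(recs, sizes = c(50, 100, 150), trait = trait))
  expect_equal(dim(rb$estimates), c(3, 3))
  expect_equal(unname(rb$sd_estimate),
               unname(apply(rb$estimates, 1, sd, na.rm = TRUE)))
  expect_length(rb$rho, 3)

  # an infeasible bin size is skipped with a warning, not an error
  expect_warning(
    rb2 <- binsize_robustness(recs[1], sizes = c(50, 5000)),
    "skipped")
  expect_true(is.na(rb2$estimates[1, "5000"]))
})
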