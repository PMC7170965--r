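test_that("Poisson MLE is the sample mean with matching log-likelihood", {
  expect_equal(fit_poisson_mle(c(5, 5, 5, 5))$lambda, 5)
  z <- fit_poisson_mle(c(0, 0, 0))
  expect_equal(z$lambda, 0)
  expect_equal(z$loglik, 0) # 0 * log 0 = 0 convention
  f <- fit_poisson_mle(c(2, 4, 6))
  expect_equal(f$lambda, 4)
  # independent density evaluation
  expect_equal(f$loglik, sum(log(exp(-4) * 4^c(2, 4, 6) /
                                   factorial(c(2, 4, 6)))))
  expect_error(fit_poisson_mle(3), "2 observations")
})

test_that("NB MLE hits the boundary for underdispersed data and nests Poisson", {
  f <- fit_negbin_mle(c(10, 10, 10, 10))
  expect_equal(f$phi, 0)
  expect_true(f$boundary)
  expect_equal(f$loglik, fit_poisson_mle(c(10, 10, 10, 10))$loglik)

  set.seed(4)
  y <- rnbinom(500, mu = 100, size = 1 / 0.3)
  f2 <- fit_negbin_mle(y)
  expect_gte(f2$phi, 0.24)
  expect_lte(f2$phi, 0.36)
  expect_equal(f2$mu, mean(y))
  # NB log-likelihood at tiny phi agrees with Poisson to 1e-6
  ll_nb <- sum(dnbinom(c(3, 5, 7), mu = 5, size = 1e10, log = TRUE))
  ll_pois <- sum(dpois(c(3, 5, 7), 5, log = TRUE))
  expect_lt(abs(ll_nb - ll_pois), 1e-6)
})

test_that("the Poisson bootstrap flags overdispersed data, NB does not", {
  sim <- simulate_experiment(simulation_config(
    n_genes = 25, peaks_per_gene = 1, n_replicates_per_condition = 3,
    baseline_gene_mean = 150, dispersion = c(0.5, 0),
    library_size_factors = rep(1, 12), replicate_pair_sd = 0, seed = 6))
  rep_pois <- bootstrap_loglik_percentile(sim$experiment, "poisson",
                                          n_sim = 200, seed = 9)
  rep_nb <- bootstrap_loglik_percentile(sim$experiment, "negbin",
                                        n_sim = 200, seed = 9)
  expect_equal(rep_pois$percentile_of_observed, 0)
  expect_gt(rep_nb$percentile_of_observed, 0)
  expect_length(rep_nb$simulated_mean_logliks, 200)

  # determinism and invariance to peak order
  rep2 <- bootstrap_loglik_percentile(sim$experiment, "poisson",
                                      n_sim = 200, seed = 9)
  expect_identical(rep_pois$simulated_mean_logliks,
                   rep2$simulated_mean_logliks)
  exp_rev <- sim$experiment
  ord <- rev(seq_len(nrow(exp_rev$peak_counts)))
  exp_rev$peak_counts <- exp_rev$peak_counts[ord, ]
  exp_rev$peaks <- exp_rev$peaks[ord, ]
  rep_rev <- bootstrap_loglik_percentile(exp_rev, "poisson",
                                         n_sim = 200, seed = 9)
  expect_equal(rep_rev$percentile_of_observed,
               rep_pois$percentile_of_observed)
  expect_equal(rep_rev$observed_mean_loglik, rep_pois$observed_mean_loglik)

  expect_error(bootstrap_loglik_percentile(sim$experiment, "poisson",
                                           n_sim = 10), "meaningless")
})

test_that("overdispersion summary reads the mean-variance relationship", {
  # constant rows: variance 0 < mean
  exp_const <- make_experiment(matrix(50L, 4, 8))
  s <- overdispersion_summary(exp_const)
  expect_true(all(s$moments$variance == 0))
  expect_equal(s$fraction_overdispersed, 0)

  # strongly overdispersed NB data: nearly all peak-cells overdispersed
  set.seed(12)
  m <- matrix(rnbinom(50 * 48, mu = 100, size = 1 / 0.3), 50, 48)
  exp_od <- make_experiment(m, n_rep = 12)
  s_od <- overdispersion_summary(exp_od)
  expect_gt(s_od$fraction_overdispersed, 0.9)

  # Poisson data: moment estimator is symmetric around var = mean
  m_p <- matrix(rpois(200 * 24, 100), 200, 24)
  exp_p <- make_experiment(m_p, n_rep = 6)
  s_p <- overdispersion_summary(exp_p)
  expect_gt(s_p$fraction_overdispersed, 0.35)
  expect_lt(s_p$fraction_overdispersed, 0.65)
})
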