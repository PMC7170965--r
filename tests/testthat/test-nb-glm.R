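samples8 <- make_samples(2)
design8 <- glm_design(samples8)

test_that("saturated cell means give closed-form coefficients", {
  # input-control 10, input-treated 10, IP-control 20, IP-treated 40
  y <- ifelse(samples8$fraction == "input", 10,
              ifelse(samples8$condition == "control", 20, 40))
  for (phi in c(0, 0.1)) {
    f <- fit_nb_glm(y, design8, phi, "full")
    expect_equal(unname(f$coefficients),
                 c(log(10), log(2), 0, log(2)), tolerance = 1e-7)
    # one parameter per cell + equal offsets: fitted means = cell means
    expect_equal(unname(f$fitted), y, tolerance = 1e-6)
  }
})

test_that("a treated group copying control yields a zero interaction", {
  set.seed(1)
  y_ctl <- rpois(4, c(30, 30, 90, 90))
  y <- numeric(8)
  y[samples8$condition == "control"] <- y_ctl
  y[samples8$condition == "treated"] <- y_ctl
  f <- fit_nb_glm(y, design8, 0.05, "full")
  expect_equal(unname(f$coefficients["beta_interaction"]), 0,
               tolerance = 1e-7)
})

test_that("model nesting: full deviance never exceeds reduced", {
  set.seed(7)
  for (i in 1:20) {
    y <- rnbinom(8, mu = 50, size = 5)
    full <- fit_nb_glm(y, design8, 0.2, "full")
    red <- fit_nb_glm(y, design8, 0.2, "reduced")
    expect_lte(full$deviance, red$deviance + 1e-6)
    t <- lrt_interaction(full, red)
    expect_gte(t$lrt_stat, 0)
    expect_true(t$p_value >= 0 && t$p_value <= 1)
  }
})

test_that("the chi-squared df=1 tail matches an independent evaluation", {
  f <- list(deviance = 0, converged = TRUE, degenerate = FALSE)
  r <- list(deviance = 3.8415, converged = TRUE, degenerate = FALSE)
  t <- lrt_interaction(f, r)
  # chi2(1) upper tail via the normal distribution: P(|Z| > sqrt(x))
  expect_equal(t$p_value, 2 * pnorm(sqrt(3.8415), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(t$p_value, 4), 0.05)

  t0 <- lrt_interaction(f, list(deviance = 0, converged = TRUE,
                                degenerate = FALSE))
  expect_equal(t0$lrt_stat, 0)
  expect_equal(t0$p_value, 1)

  # non-converged fits propagate missing p
  bad <- list(deviance = 1, converged = FALSE, degenerate = FALSE)
  expect_true(is.na(lrt_interaction(bad, r)$p_value))
})

test_that("the NB fit approaches the Poisson fit as dispersion vanishes", {
  set.seed(11)
  y <- rpois(8, c(20, 60, 20, 60, 25, 70, 25, 70))
  f_nb <- fit_nb_glm(y, design8, 1e-10, "full")
  f_pois <- stats::glm(y ~ design8$X_full - 1, family = poisson())
  expect_equal(unname(f_nb$coefficients), unname(coef(f_pois)),
               tolerance = 1e-6)
})

test_that("IRLS coefficients match brute-force likelihood maximization", {
  set.seed(23)
  offset <- log(runif(8, 0.7, 1.4))
  for (i in 1:10) {
    y <- rnbinom(8, mu = exp(log(40) + design8$X_full %*% rnorm(4, 0, 0.5)
                             + offset), size = 1 / 0.15)
    d <- list(X_full = design8$X_full, X_reduced = design8$X_reduced,
              offset = offset)
    f <- fit_nb_glm(y, d, 0.15, "full")
    oracle <- optim_nb_fit(y, design8$X_full, offset, 0.15)
    expect_equal(unname(f$coefficients), oracle, tolerance = 1e-4)
  }
})

test_that("IRLS agrees with the standard NB GLM fitter at fixed dispersion", {
  set.seed(31)
  y <- rnbinom(8, mu = 80, size = 10)
  f <- fit_nb_glm(y, design8, 0.1, "full")
  ref <- suppressWarnings(stats::glm(
    y ~ design8$X_full - 1, family = MASS::negative.binomial(theta = 10)))
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-5)
})

test_that("swapping condition labels flips the interaction sign, not the test", {
  sim <- simulate_experiment(simulation_config(
    n_genes = 10, n_replicates_per_condition = 3, fraction_changed = 0.5,
    methylation_log2fc = 1.5, seed = 13))
  exp1 <- sim$experiment
  exp2 <- exp1
  exp2$samples$condition <- ifelse(exp2$samples$condition == "control",
                                   "treated", "control")
  sf <- estimate_size_factors(exp1)
  d1 <- glm_design(exp1$samples, sf)
  d2 <- glm_design(exp2$samples, sf)
  disp <- estimate_dispersions(exp1, d1, "trend_shrink")
  r1 <- glm_lrt(exp1, d1, disp)
  disp2 <- estimate_dispersions(exp2, d2, "trend_shrink")
  r2 <- glm_lrt(exp2, d2, disp2)
  expect_equal(r1$beta_interaction, -r2$beta_interaction, tolerance = 1e-4)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-4)
})

test_that("degenerate all-zero peaks are excluded from testing", {
  m <- matrix(20L, 3, 8)
  m[2, ] <- 0L
  exp <- make_experiment(m)
  sf <- estimate_size_factors(exp)
  d <- glm_design(exp$samples, sf)
  disp <- estimate_dispersions(exp, d, "trend_shrink")
  res <- glm_lrt(exp, d, disp)
  expect_true(is.na(res$p_value[2]))
  expect_false(res$converged[2])
  expect_true(all(!is.na(res$p_value[c(1, 3)])))
})

test_that("designs missing a cell are rejected with an actionable message", {
  s <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    fraction = c("input", "IP", "input", "IP"),
    condition = "control",
    replicate = c(1L, 1L, 2L, 2L))
  expect_error(glm_design(s), "four IP/input")
})
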