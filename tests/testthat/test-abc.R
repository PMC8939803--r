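test_that("rejection ABC with infinite tolerance recovers the prior", {
  prior <- toy_prior()
  post <- abc_rejection(0, prior = prior, proj = NULL, epsilon = Inf,
                        n_accept = 500, simulator = toy_gaussian_simulator,
                        seed = 1)
  expect_equal(nrow(post$samples), 500)
  b <- prior$bounds
  for (j in seq_len(7)) {
    ks <- suppressWarnings(
      stats::ks.test(post$samples[, j], "punif", b[j, 1], b[j, 2]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("a point-mass prior returns only that point", {
  prior <- prior_spec(p_Ad = c(5, 5), p_Ag = c(1, 1), p_T = c(1, 1),
                      p_F = c(1, 1), a_T = c(2, 2), vzAP = c(1e-4, 1e-4),
                      vzNAP = c(1e-4, 1e-4))
  post <- abc_rejection(5, prior = prior, epsilon = Inf, n_accept = 20,
                        simulator = function(th) th[[1]], seed = 2)
  expect_true(all(post$samples[, "p_Ad"] == 5))
  expect_true(all(post$samples[, "a_T"] == 2))
})

test_that("the indicator kernel concentrates a deterministic toy posterior", {
  # y = theta[1] exactly; acceptance region is (y0 - eps, y0 + eps)
  post <- abc_rejection(10, prior = toy_prior(), epsilon = 0.5,
                        n_accept = 100, max_draws = 50000,
                        simulator = function(th) th[[1]], seed = 3)
  expect_true(all(abs(post$samples[, 1] - 10) < 0.5))
  expect_error(abc_rejection(10, prior = toy_prior(), epsilon = 1e-9,
                             n_accept = 5, max_draws = 50,
                             simulator = function(th) th[[1]], seed = 1),
               "epsilon")
})

test_that("rejection acceptance rate is monotone in the tolerance", {
  rates <- vapply(c(0.5, 1, 2, 4), function(eps) {
    abc_rejection(10, prior = toy_prior(), epsilon = eps, n_accept = 10000,
                  max_draws = 2000, simulator = toy_gaussian_simulator,
                  seed = 99)$acceptance_rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("SABC matches the conjugate Gaussian posterior mean", {
  # uniform[0, 20] prior on theta1, y ~ N(theta1, 1), y0 = 10 central:
  # the posterior is N(10, 1) truncated far from the bounds, mean 10
  prior <- toy_prior()
  # Monte-Carlo error estimated from independent sampler replicates (the
  # annealed population is internally correlated, so a within-run standard
  # error would understate it)
  means <- vapply(1:5, function(r) {
    p <- sabc_sample(10, prior = prior, n_particles = 510,
                     n_generations = 20,
                     simulator = toy_gaussian_simulator, seed = 500 + r)
    mean(p$samples[, 1])
  }, numeric(1))
  mcse <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 10), 4.6 * mcse) # t(4) at the 1% level
  # irrelevant coordinates stay prior-distributed (wide)
  p1 <- sabc_sample(10, prior = prior, n_particles = 510,
                    n_generations = 20,
                    simulator = toy_gaussian_simulator, seed = 501)
  expect_gt(stats::sd(p1$samples[, "vzNAP"]), 1e-4)
})

test_that("SABC anneals: median distance is almost always non-increasing", {
  drops <- 0L; total <- 0L
  for (s in 1:10) {
    post <- sabc_sample(10, prior = toy_prior(), n_particles = 64,
                        n_generations = 10,
                        simulator = toy_gaussian_simulator, seed = 200 + s)
    tr <- post$generation_median_distance
    drops <- drops + sum(diff(tr) <= 1e-12)
    total <- total + length(tr) - 1
  }
  expect_gte(drops / total, 0.85)
})

test_that("SABC is reproducible and respects the prior support", {
  a <- sabc_sample(10, prior = toy_prior(), n_particles = 32,
                   n_generations = 5, simulator = toy_gaussian_simulator,
                   seed = 7)
  b <- sabc_sample(10, prior = toy_prior(), n_particles = 32,
                   n_generations = 5, simulator = toy_gaussian_simulator,
                   seed = 7)
  expect_identical(a$samples, b$samples)
  bnd <- toy_prior()$bounds
  for (j in 1:7)
    expect_true(all(a$samples[, j] >= bnd[j, 1] &
                      a$samples[, j] <= bnd[j, 2]))
})

test_that("warm starts and reference tables feed the same machinery", {
  tab <- reference_table(prior = toy_prior(), n = 400,
                         simulator = toy_gaussian_simulator, seed = 11)
  post0 <- abc_rejection_table(8, tab, n_accept = 50)
  expect_equal(nrow(post0$samples), 50)
  expect_true(all(diff(sort(post0$distances)) >= 0))
  post <- sabc_sample(8, prior = toy_prior(), n_particles = 50,
                      n_generations = 4, init_samples = post0,
                      simulator = toy_gaussian_simulator, seed = 12)
  expect_lt(abs(mean(post$samples[, 1]) - 8), 1)
})

test_that("the fitted model object exposes the standard methods", {
  cfg <- fast_config()
  th0 <- base_params()
  obs <- simulate_deposition(th0, cfg, seed = 77)
  fit <- abc_fit(obs, config = cfg, method = "sabc", n_particles = 24,
                 n_generations = 3, init_factor = 2, seed = 3)
  expect_s3_class(fit, "abc_fit")
  expect_named(coef(fit), plateletABC:::param_names())
  sm <- summary(fit)
  expect_equal(dim(sm$quantiles), c(7, 5))
  ci <- credible_interval(fit)
  expect_true(all(ci[, 1] <= ci[, 2]))
  expect_output(print(fit), "MAP")
  ens <- simulate(fit, nsim = 5, seed = 1)
  expect_length(ens, 5)
  expect_s3_class(ens[[1]], "deposition_series")
  r <- residuals(fit, nsim = 12, seed = 2)
  expect_equal(nrow(r), 12)
  expect_equal(r$residual, r$observed - r$predicted)
})
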