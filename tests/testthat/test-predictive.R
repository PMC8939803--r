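make_series <- function(vals) {
  s <- data.frame(time_s = c(0, 20, 120, 300),
                  n_clusters_per_mm2 = vals[1:4],
                  mean_cluster_size_cells = vals[5:8],
                  n_platelet_per_ul = vals[9:12])
  class(s) <- c("deposition_series", "data.frame")
  s
}

test_that("credible bands are pointwise empirical quantiles", {
  one <- make_series(rep(c(1, 2, 3), each = 4))
  band <- credible_band(rep(list(one), 25))
  expect_equal(band$lower, band$upper)
  expect_equal(band$median, band$lower)

  # 100 distinct values at one point: R type-7 quantiles at 2.5/50/97.5%
  ens <- lapply(1:100, function(i) make_series(c(i, rep(0, 11))))
  band <- credible_band(ens, level = 0.95)
  first <- band[band$observable == "n_clusters_per_mm2" & band$time_s == 0, ]
  expect_equal(first$lower, unname(quantile(1:100, 0.025)))
  expect_equal(first$upper, unname(quantile(1:100, 0.975)))
  expect_equal(first$median, 50.5)
})

test_that("energy score reproduces hand-evaluated instances", {
  # ensemble equal to the observation scores exactly zero
  expect_equal(energy_score(matrix(rep(3, 10), ncol = 1), 3), 0)
  # {-1, +1} vs 0: 2*(1+1) - (2+2) = 0
  expect_equal(energy_score(matrix(c(-1, 1), ncol = 1), 0), 0)
  # biased {1, 1} vs 0: 2*2 - 0 = 4
  expect_equal(energy_score(matrix(c(1, 1), ncol = 1), 0), 4)
  # normalized variant: (2/m) sum - (1/m^2) sum sum
  expect_equal(energy_score(matrix(c(-1, 1), ncol = 1), 0, normalize = TRUE),
               2 * 1 - (2 + 2) / 4)
  expect_error(energy_score(matrix(1, ncol = 1), 0, beta = 2), "beta")
  expect_error(energy_score(matrix(1, ncol = 1), 0, beta = 0), "beta")
})

test_that("energy score approaches its squared-bias form as beta -> 2", {
  set.seed(2)
  xs <- matrix(rnorm(40), ncol = 1)
  x0 <- 0.7
  analytic <- 2 * sum((xs - x0)^2) - sum(outer(drop(xs), drop(xs), "-")^2)
  expect_equal(energy_score(xs, x0, beta = 1.9999), analytic,
               tolerance = 1e-3)
})

test_that("the score grows with ensemble bias at fixed dispersion", {
  set.seed(8)
  base <- rnorm(60, 0, 1)
  scores <- vapply(c(0, 1, 2, 4), function(mu)
    energy_score(matrix(base + mu, ncol = 1), 0), numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("per-observable scores carry raw units and pool with z-scoring", {
  set.seed(10)
  ens <- lapply(1:30, function(i)
    make_series(abs(rnorm(12, mean = rep(c(100, 10, 1e5), each = 4)))))
  obs <- make_series(rep(c(100, 10, 1e5), each = 4))
  es <- energy_score(ens, obs)
  expect_named(es$per_observable,
               c("n_clusters_per_mm2", "mean_cluster_size_cells",
                 "n_platelet_per_ul"))
  expect_true(all(is.finite(es$per_observable)))
  expect_true(is.finite(es$pooled))
  # the normalized estimator of the energy distance to a point mass is
  # non-negative in expectation and here in realization
  esn <- energy_score(ens, obs, normalize = TRUE)
  expect_true(all(esn$per_observable >= 0))
})

test_that("posterior predictive draws are seeded and reproducible", {
  cfg <- fast_config()
  x <- matrix(rep(unclass(base_params()), each = 30), 30, 7)
  colnames(x) <- plateletABC:::param_names()
  post <- plateletABC:::new_posterior_samples(
    x, rep(0, 30), 1, 1, "rejection", NULL, 1)
  e1 <- posterior_predictive(post, cfg, n_draws = 4, seed = 42)
  e2 <- posterior_predictive(post, cfg, n_draws = 4, seed = 42)
  expect_identical(lapply(e1, as.data.frame), lapply(e2, as.data.frame))
  expect_error(posterior_predictive(post, cfg, n_draws = 0), ">= 1")
  expect_message(posterior_predictive(post, cfg, n_draws = 40, seed = 1),
                 "replacement")
})

test_that("bands at the true parameters cover fresh replicates", {
  cfg <- fast_config()
  th <- base_params()
  x <- matrix(rep(unclass(th), each = 40), 40, 7)
  colnames(x) <- plateletABC:::param_names()
  post <- plateletABC:::new_posterior_samples(
    x, rep(0, 40), 1, 1, "rejection", NULL, 1)
  ens <- posterior_predictive(post, cfg, n_draws = 40, seed = 3)
  band <- credible_band(ens, level = 0.95)
  set.seed(9)
  inside <- 0L; total <- 0L
  for (r in 1:10) {
    s <- simulate_deposition(th, cfg)
    v <- c(s$n_clusters_per_mm2, s$mean_cluster_size_cells,
           s$n_platelet_per_ul)
    lo <- band$lower; hi <- band$upper
    inside <- inside + sum(v >= lo - 1e-9 & v <= hi + 1e-9)
    total <- total + length(v)
  }
  expect_gte(inside / total, 0.9)
})
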