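test_that("polynomial expansion reproduces the stated layout", {
  ex <- feature_expansion(standardize = FALSE)
  expect_equal(expand_features(c(2, 3), ex), c(2, 3, 4, 9, 8, 27, 6))
  expect_equal(expand_features(c(0, 0, 0), ex), rep(0, 12))
  d <- length(expand_features(rep(1, 4), ex))
  expect_equal(expand_features(rep(1, 4), ex), rep(1, d))
  expect_equal(d, 4 * 3 + choose(4, 2))
  expect_error(expand_features(c(1, NaN), ex), "non-finite")
  # standardizing expansion without training constants is refused
  expect_error(expand_features(c(1, 2), feature_expansion()), "constants")
})

test_that("summary distance is a pseudo-metric with hand-checkable values", {
  set.seed(1)
  x <- matrix(rnorm(60), 10, 6)
  proj <- identity_projection(x)
  expect_equal(summary_distance(x[1, ], x[1, ], proj), 0)
  # order-1 identity projection on unscaled features gives plain Euclid
  proj_raw <- proj
  proj_raw$expansion <- feature_expansion(orders = 1, cross_products = FALSE,
                                          standardize = FALSE)
  expect_equal(summary_distance(c(3, 0, 0, 0, 0, 0),
                                c(0, -4, 0, 0, 0, 0), proj_raw), 5)
  # triangle inequality over random triples under a random projection
  L <- matrix(rnorm(12), 2, 6)
  projL <- proj_raw; projL$L <- L
  ok <- TRUE
  for (k in 1:1000) {
    tri <- matrix(rnorm(18), 3, 6)
    d12 <- summary_distance(tri[1, ], tri[2, ], projL)
    d23 <- summary_distance(tri[2, ], tri[3, ], projL)
    d13 <- summary_distance(tri[1, ], tri[3, ], projL)
    ok <- ok && (d13 <= d12 + d23 + 1e-12)
  }
  expect_true(ok)
  expect_error(summary_distance(1:3, 1:4), "length")
})

test_that("metric learning separates separable groups and is reproducible", {
  # two groups 10+ within-SDs apart along feature 1, noise elsewhere
  set.seed(42)
  n <- 20
  x <- cbind(c(rnorm(n, 0, 1), rnorm(n, 15, 1)), matrix(rnorm(2 * n * 5), 2 * n, 5))
  y <- rep(c("a", "b"), each = n)
  fit <- fit_discriminative_projection(list(x = x, group = y),
                                       k_neighbors = 3, seed = 7)
  pts <- t(apply(x, 1, project_summary, proj = fit))
  expect_equal(plateletABC:::cluster_rand_index(pts, y), 1.0)
  # M = L'L positive semi-definite
  M <- crossprod(fit$L)
  expect_true(all(eigen(M, symmetric = TRUE, only.values = TRUE)$values >=
                    -1e-8))
  fit2 <- fit_discriminative_projection(list(x = x, group = y),
                                        k_neighbors = 3, seed = 7)
  expect_identical(fit$L, fit2$L)
  expect_error(fit_discriminative_projection(list(x = x, group = y),
                                             k_neighbors = n), "smaller")
})

test_that("rand index counts pair agreements", {
  expect_equal(rand_index(c(1, 1, 2), c(1, 2, 2)), 1 / 3)
  expect_equal(rand_index(c(1, 2, 1, 2), c(5, 6, 5, 6)), 1)
  expect_equal(rand_index(rep(1, 4), c(1, 1, 2, 2)), 1 / 3 * 2 / 2)
})

test_that("hyperparameter tuning maximizes the clustering rand index", {
  set.seed(8)
  n <- 12
  x <- cbind(c(rnorm(n, 0, 1), rnorm(n, 12, 1), rnorm(n, -12, 1)),
             matrix(rnorm(3 * n * 4), 3 * n, 4))
  y <- rep(c("g1", "g2", "g3"), each = n)
  tuned <- tune_projection_by_rand_index(
    list(x = x, group = y),
    candidates = list(list(k_neighbors = 2), list(k_neighbors = 4)),
    seed = 3)
  expect_equal(tuned$rand_index, 1.0)
  expect_true(tuned$candidate %in% 1:2)
  expect_error(tune_projection_by_rand_index(list(x = x, group = y),
                                             candidates = list()), "empty")
})

test_that("null cohorts do not tune to spuriously high rand index", {
  # three identically distributed groups: held-out clustering agreement
  # stays near chance (in-sample the metric can memorize noise directions,
  # which is why the tuner offers split validation)
  scores <- vapply(1:10, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(48 * 6), 48, 6)
    y <- rep(c("a", "b", "c"), each = 16)
    tuned <- tune_projection_by_rand_index(
      list(x = x, group = y),
      candidates = list(list(k_neighbors = 3, n_iter = 60)), seed = s,
      validate = "split")
    tuned$rand_index
  }, numeric(1))
  expect_lte(stats::median(scores), 0.6)
})

test_that("feature scaling cancels out of standardized distances", {
  set.seed(9)
  x <- matrix(rnorm(40), 10, 4)
  p1 <- identity_projection(x)
  p2 <- identity_projection(x * 100)
  d1 <- summary_distance(x[1, ], x[2, ], p1)
  d2 <- summary_distance(x[1, ] * 100, x[2, ] * 100, p2)
  expect_equal(d1, d2)
})
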