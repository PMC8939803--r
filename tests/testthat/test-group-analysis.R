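test_that("Kruskal-Wallis reproduces hand-computed statistics", {
  # rank sums 6, 15, 24 over N = 9: H = 12/(N(N+1)) sum R^2/n - 3(N+1) = 7.2
  hw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(unname(hw["H"]), 7.2)
  # perfectly tie-symmetric groups: H = 0, p = 1
  hw2 <- kruskal_wallis(list(c(1, 2), c(1, 2)))
  expect_equal(unname(hw2["H"]), 0)
  expect_equal(unname(hw2["p"]), 1)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
  expect_error(kruskal_wallis(list(1, 1:3)), "at least 2")
})

test_that("Kruskal-Wallis holds its nominal type-I error", {
  set.seed(17)
  rej <- mean(replicate(1000, {
    kruskal_wallis(list(rnorm(16), rnorm(16), rnorm(16)))["p"] < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(3)
  g <- list(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  h1 <- kruskal_wallis(g)
  h2 <- kruskal_wallis(lapply(g, function(x) exp(x / 3)))
  expect_equal(h1, h2)
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  p <- c(0.001, 0.2, 0.04)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

fake_map_table <- function(centers, n = 8, sd = 1, seed = 1) {
  set.seed(seed)
  labs <- names(centers)
  out <- do.call(rbind, lapply(labs, function(g) {
    m <- matrix(rnorm(n * 7, mean = rep(centers[[g]], each = n), sd = sd),
                n, 7)
    colnames(m) <- plateletABC:::param_names()
    data.frame(subject_id = paste0(g, seq_len(n)), group = g, m)
  }))
  out
}

test_that("parameters whose centres differ are the ones flagged", {
  base <- c(50, 15, 1, 0.2, 6, 3, 3)
  centers <- list(A = base, B = replace(base, 2, 15 + 8)) # p_Ag +8 sd
  tab <- fake_map_table(centers, sd = 1, seed = 2)
  res <- identify_discriminating_parameters(tab)
  disc <- attr(res, "discriminating")
  expect_equal(disc[["all"]], "p_Ag")
  expect_s3_class(res, "group_tests")
  expect_true(all(res$p_adj >= res$p))
})

test_that("identically generated groups rarely flag anything", {
  base <- c(50, 15, 1, 0.2, 6, 3, 3)
  centers <- list(A = base, B = base, C = base)
  n_flagged <- vapply(1:60, function(s) {
    tab <- fake_map_table(centers, sd = 1, seed = 400 + s)
    length(unlist(attr(identify_discriminating_parameters(tab),
                       "discriminating")))
  }, numeric(1))
  expect_gte(mean(n_flagged == 0), 0.9)
})

test_that("nearest-median classification follows its conventions", {
  expect_equal(classify_pathology(0, 0, 10), "healthy")
  expect_equal(classify_pathology(9, 0, 10), "disease")
  expect_equal(classify_pathology(5, 0, 10), "healthy") # tie -> healthy
  expect_equal(classify_pathology(c(1, 9), 0, 10),
               c("healthy", "disease"))
  expect_error(classify_pathology(1, 3, 3), "equal")
  expect_error(classify_pathology(1, NaN, 3), "finite")
})

test_that("sensitivity and specificity count the right cells", {
  truth <- rep(c("d", "h"), each = 16)
  expect_equal(unname(sensitivity_specificity(truth, truth, "d")), c(1, 1))
  all_h <- rep("h", 32)
  expect_equal(unname(sensitivity_specificity(all_h, truth, "d")), c(0, 1))
  preds <- c(rep("d", 12), rep("h", 4), rep("h", 12), rep("d", 4))
  expect_equal(unname(sensitivity_specificity(preds, truth, "d")),
               c(0.75, 0.75))
  expect_error(sensitivity_specificity(all_h, rep("h", 32), "d"), "classes")
})

test_that("the pathology test separates shifted groups end to end", {
  base <- c(50, 15, 1, 0.2, 6, 3, 3)
  centers <- list(healthy = base, copd = replace(base, 2, 15 + 10))
  tab <- fake_map_table(centers, n = 16, sd = 1, seed = 5)
  pt <- pathology_test(tab, "p_Ag", "healthy", "copd")
  expect_gte(pt$metrics[["sensitivity"]], 0.9)
  expect_gte(pt$metrics[["specificity"]], 0.9)
  # leave-one-out medians change nothing for well-separated groups
  pt_loo <- pathology_test(tab, "p_Ag", "healthy", "copd",
                           leave_one_out = TRUE)
  expect_equal(pt$metrics, pt_loo$metrics)
})
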