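test_that("disruption index is the OLS slope of difference on reference", {
  ref <- seq(0.1, 0.9, length.out = 12)

  expect_equal(coreness_disruption_index(ref, ref)$kappa, 0)
  expect_equal(coreness_disruption_index(ref, 0.8 * ref)$kappa, -0.2)

  # proportional inflation: kappa(ref, ref + b*ref) = b
  for (b in c(-0.35, 0.12, 1.4))
    expect_equal(coreness_disruption_index(ref, ref + b * ref)$kappa, b)

  # random vectors vs closed-form normal equations
  set.seed(141)
  x <- stats::runif(20); y <- stats::runif(20)
  d <- y - x
  slope <- sum((x - mean(x)) * (d - mean(d))) / sum((x - mean(x))^2)
  fit <- coreness_disruption_index(x, y)
  expect_equal(fit$kappa, slope)
  expect_equal(fit$per_node_diff, d)
  expect_true(fit$p_value >= 0 && fit$p_value <= 1)

  expect_error(coreness_disruption_index(rep(0.5, 10), stats::runif(10)),
               "constant")
  expect_error(coreness_disruption_index(1:3, 1:4), "equal length")
})

test_that("individual disruption decreases with planted severity", {
  set.seed(142)
  ref <- stats::runif(30, 0.2, 0.9)
  sev <- stats::runif(15)
  kappas <- vapply(sev, function(a)
    individual_disruption(ref * (1 - a) +
                            stats::rnorm(30, 0, 0.01), ref)$kappa,
    numeric(1))
  expect_equal(individual_disruption(ref, ref)$kappa, 0)
  expect_equal(individual_disruption(ref * 0.7, ref)$kappa, -0.3)
  expect_lt(stats::cor(sev, kappas, method = "spearman"), 0)
})

test_that("permutation t test matches exact enumeration and edge cases", {
  # identical multisets: observed t = 0, p = 1
  expect_equal(permutation_ttest(c(1, 2, 3), c(3, 1, 2), n_perm = 200,
                                 seed = 1), 1)

  # 3 vs 3 toy data: exact enumeration over all 20 assignments
  a <- c(1.2, 2.1, 0.7); b <- c(2.9, 3.4, 2.2)
  p_exact <- permutation_ttest(a, b, exact = TRUE)
  pooled <- c(a, b)
  tt <- function(ia) {
    x <- pooled[ia]; y <- pooled[-ia]
    abs((mean(x) - mean(y)) /
          sqrt(stats::var(x) / 3 + stats::var(y) / 3))
  }
  tstar <- apply(utils::combn(6, 3), 2, tt)
  expect_equal(p_exact, mean(tstar >= tt(1:3) - 1e-12))

  # widely separated groups reach the minimal attainable p
  set.seed(151)
  p <- permutation_ttest(stats::rnorm(8, 0, 0.1),
                         stats::rnorm(8, 100, 0.1), n_perm = 999, seed = 2)
  expect_equal(p, 1 / 1000)

  expect_warning(p0 <- permutation_ttest(rep(1, 4), rep(1, 5), n_perm = 99),
                 "zero pooled variance")
  expect_equal(p0, 1)
  expect_error(permutation_ttest(1, c(1, 2)), "at least 2")

  # reproducibility
  set.seed(152)
  x <- stats::rnorm(6); y <- stats::rnorm(6, 1)
  expect_identical(permutation_ttest(x, y, n_perm = 299, seed = 7),
                   permutation_ttest(x, y, n_perm = 299, seed = 7))
})

test_that("permutation p-values are valid under the null", {
  # both groups from the same distribution: rate of p < 0.05 within
  # binomial 99% bounds of 0.05 over 2000 simulated node-tests
  set.seed(161)
  n_tests <- 2000
  A <- matrix(stats::runif(10 * n_tests), 10, n_tests)
  B <- matrix(stats::runif(12 * n_tests), 12, n_tests)
  tab <- regional_comparison(cohort_coreness(A, B),
                             stats_config(n_permutations = 399, seed = 9))
  rate <- mean(tab$p < 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / n_tests)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("rough FDR threshold follows alpha (n+1) / (2n)", {
  expect_equal(round(rough_fdr_threshold(0.05, 68), 3), 0.025)
  expect_equal(rough_fdr_threshold(0.05, 1), 0.05)
  expect_gt(rough_fdr_threshold(0.05, 1e6), 0.025)
  expect_lt(rough_fdr_threshold(0.05, 1e6), 0.0251)
  expect_error(rough_fdr_threshold(1.2, 10), "alpha")
})

test_that("behavior correlations are rank-based with pairwise deletion", {
  expect_equal(behavior_correlations(1:8, (1:8)^3)$rho, 1)
  expect_equal(behavior_correlations(1:8, -(1:8)^3)$rho, -1)

  # ties: average-rank then product-moment oracle
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 3, 3, 5, 6)
  got <- behavior_correlations(x, y)
  expect_equal(got$rho, stats::cor(rank(x), rank(y)))

  # pairwise deletion of missing scores
  got <- behavior_correlations(1:6, c(1, 2, NA, 4, 5, 6))
  expect_equal(got$n, 5)
  expect_equal(got$rho, 1)

  expect_error(behavior_correlations(1:3, c(1, 2, NA)), "fewer than 4")
  expect_error(behavior_correlations(1:5, rep(2, 5)), "constant")
})

test_that("regional comparison flags planted node shifts", {
  set.seed(171)
  # identical groups: nothing significant
  X <- matrix(stats::runif(8 * 10), 8, 10)
  tab <- regional_comparison(cohort_coreness(X, X),
                             stats_config(n_permutations = 199, seed = 3))
  expect_equal(nrow(tab), 10)
  expect_equal(sum(tab$significant), 0)
  expect_equal(attr(tab, "alpha_fdr"), rough_fdr_threshold(0.05, 10))

  # the strongly shifted node is flagged in every seed; null nodes are
  # flagged only at the rate the discrete permutation p-values allow
  extra <- 0L
  for (s in 1:10) {
    set.seed(200 + s)
    A <- matrix(stats::runif(8 * 10, 0.4, 0.6), 8, 10)
    B <- matrix(stats::runif(8 * 10, 0.4, 0.6), 8, 10)
    B[, 4] <- stats::runif(8, 0.0, 0.05)
    tab <- regional_comparison(cohort_coreness(A, B),
                               stats_config(n_permutations = 999,
                                            seed = 300 + s))
    expect_true(tab$significant[4])
    extra <- extra + sum(tab$significant) - 1L
  }
  # 90 null node-tests at alpha_fdr = 0.0275: a handful of false flags
  expect_lte(extra, 5L)
})
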