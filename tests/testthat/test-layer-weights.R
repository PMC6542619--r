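test_that("hypersphere angles map to nonnegative unit coefficients", {
  expect_equal(angles_to_coefficients(rep(0, 8))$values, c(rep(0, 8), 1))
  expect_equal(angles_to_coefficients(rep(pi / 2, 8))$values, c(1, rep(0, 8)))
  expect_error(angles_to_coefficients(c(0.1, -0.2)), "\\[0, pi/2\\]")
  expect_error(angles_to_coefficients(c(0.1, 2)), "\\[0, pi/2\\]")

  set.seed(101)
  for (i in 1:1000) {
    phi <- stats::runif(sample(1:8, 1), 0, pi / 2)
    v <- angles_to_coefficients(phi)$values
    expect_true(all(v >= 0))
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
  }
})

test_that("angle recovery round-trips over the positive octant", {
  set.seed(102)
  for (i in 1:200) {
    M <- sample(2:9, 1)
    v <- abs(stats::rnorm(M))
    v <- v / sqrt(sum(v^2))
    phi <- coefficients_to_angles(v)
    expect_true(all(phi >= 0 & phi <= pi / 2))
    expect_equal(angles_to_coefficients(phi)$values, v, tolerance = 1e-9)
  }
})

test_that("Fisher criterion separates group means against dispersion", {
  A <- matrix(c(0.2, 0.4, 0.3, 0.5), 2, 2, byrow = TRUE)
  expect_equal(fisher_criterion(cohort_coreness(A, A)), 0)

  # 2 + 2 subjects, 2 nodes, hand-computed ratio
  B <- matrix(c(0.6, 0.1, 0.7, 0.2), 2, 2, byrow = TRUE)
  ma <- colMeans(A); mb <- colMeans(B)
  num <- sum((ma - mb)^2)
  sa <- sum((A[1, ] - ma)^2) + sum((A[2, ] - ma)^2)
  sb <- sum((B[1, ] - mb)^2) + sum((B[2, ] - mb)^2)
  expect_equal(fisher_criterion(cohort_coreness(A, B)), num / (sa + sb))

  # degenerate: distinct means with zero dispersion
  Z1 <- matrix(0.2, 2, 3); Z2 <- matrix(0.8, 2, 3)
  expect_error(fisher_criterion(cohort_coreness(Z1, Z2)), "degenerate")
  expect_error(cohort_coreness(A[1, , drop = FALSE], B), "at least 2")

  # invariance to a consistent node permutation
  set.seed(111)
  A <- matrix(stats::runif(12), 3, 4); B <- matrix(stats::runif(16), 4, 4)
  perm <- sample(4)
  expect_equal(fisher_criterion(cohort_coreness(A, B)),
               fisher_criterion(cohort_coreness(A[, perm], B[, perm])))
})

test_that("coreness-based F is invariant to coefficient scale", {
  set.seed(112)
  nets <- lapply(1:6, function(i) rand_multiplex(8, 2))
  grp <- rep(c("a", "b"), each = 3)
  co <- mcp_cohort(nets, grp)
  cv <- c(0.3, 0.9)
  f1 <- fisher_criterion(coreplex:::cohort_coreness_at(co, cv))
  f2 <- fisher_criterion(coreplex:::cohort_coreness_at(co, 5 * cv))
  expect_identical(f1, f2)
})

test_that("candidate evaluation composes angles, coreness and F", {
  set.seed(121)
  netA <- rand_multiplex(8, 2)
  # identical subjects in both groups: F = 0 for any angle
  co <- mcp_cohort(list(netA, netA, netA, netA), c("a", "a", "b", "b"))
  expect_equal(evaluate_candidate(co, 0.3), 0)

  # composition identity
  nets <- lapply(1:6, function(i) rand_multiplex(8, 2))
  co <- mcp_cohort(nets, rep(c("a", "b"), each = 3))
  phi <- 0.7
  cv <- angles_to_coefficients(phi)
  expect_equal(evaluate_candidate(co, phi),
               fisher_criterion(coreplex:::cohort_coreness_at(co, cv)))

  # a planted effect in layer 2 scores higher one-hot on layer 2 than on
  # the unaffected layer
  set.seed(122)
  mkA <- function() rand_multiplex(12, 2)
  mkB <- function() {
    net <- rand_multiplex(12, 2)
    W2 <- net$W[, , 2]
    W2[1:4, 1:4] <- pmin(1, W2[1:4, 1:4] + 0.8)  # strengthen a block
    diag(W2) <- 0
    net$W[, , 2] <- W2
    net
  }
  nets <- c(replicate(5, mkA(), simplify = FALSE),
            replicate(5, mkB(), simplify = FALSE))
  co <- mcp_cohort(nets, rep(c("a", "b"), each = 5))
  f_layer2 <- fisher_criterion(coreplex:::cohort_coreness_at(co, c(0, 1)))
  f_layer1 <- fisher_criterion(coreplex:::cohort_coreness_at(co, c(1, 0)))
  expect_gt(f_layer2, f_layer1)
})

test_that("swarm optimization finds the grid-search optimum on a toy cohort", {
  set.seed(131)
  nets <- lapply(1:8, function(i) {
    net <- rand_multiplex(10, 2)
    if (i > 4) {
      W1 <- net$W[, , 1]
      W1[1:3, 1:3] <- pmin(1, W1[1:3, 1:3] + 0.7)
      diag(W1) <- 0
      net$W[, , 1] <- W1
    }
    net
  })
  co <- mcp_cohort(nets, rep(c("a", "b"), each = 4))
  fit <- pso_optimize(co, pso_config(swarm_size = 15, max_iterations = 40,
                                     seed = 5))
  grid <- seq(0, pi / 2, by = 0.01)
  fgrid <- vapply(grid, function(p) evaluate_candidate(co, p), numeric(1))
  expect_gte(fit$F_star, 0.99 * max(fgrid))
  # the best-so-far trace never decreases
  expect_true(all(diff(fit$trace) >= 0))
  # reproducibility under a fixed seed
  fit2 <- pso_optimize(co, pso_config(swarm_size = 15, max_iterations = 40,
                                      seed = 5))
  expect_identical(fit$coefficients$values, fit2$coefficients$values)

  # identical groups: F* ~ 0 with a valid unit vector
  same <- mcp_cohort(rep(nets[1], 4), c("a", "a", "b", "b"))
  fit0 <- pso_optimize(same, pso_config(swarm_size = 8, max_iterations = 5,
                                        seed = 1))
  expect_equal(fit0$F_star, 0)
  expect_equal(sum(fit0$coefficients$values^2), 1, tolerance = 1e-9)
})

test_that("swarm optimization recovers the affected layer across seeds", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- synthetic_config(n_nodes = 40, n_core = 8, n_hc = 12, n_ad = 12,
                            layer_spec = c(l1 = "meg_like", l2 = "meg_like",
                                           l3 = "dwi_like"),
                            affected_layers = "l3",
                            severity_range = c(0.9, 1),
                            attack_reduction = 0.9, seed = s)
    study <- generate_cohort(cfg)
    co <- mcp_cohort(study$subjects, study$group)
    fit <- pso_optimize(co, pso_config(swarm_size = 12, max_iterations = 15,
                                       seed = 1000 + s))
    if (names(which.max(fit$coefficients$values)) == "l3") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
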