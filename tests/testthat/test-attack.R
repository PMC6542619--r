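test_that("attack probabilities are proportional to (complement) coreness", {
  expect_equal(node_attack_probabilities(c(1, 0, 0), "core"), c(1, 0, 0))
  expect_equal(node_attack_probabilities(c(1, 0, 0), "periphery"),
               c(0, 0.5, 0.5))
  set.seed(181)
  C <- stats::runif(10)
  expect_equal(node_attack_probabilities(C, "core"), C / sum(C))
  expect_equal(node_attack_probabilities(C, "periphery"),
               (1 - C) / sum(1 - C))
  expect_warning(p <- node_attack_probabilities(rep(0, 4), "core"),
                 "uniform")
  expect_equal(p, rep(0.25, 4))
})

test_that("the disconnection process reduces exactly L distinct pairs", {
  set.seed(191)
  net <- rand_multiplex(10, 2)
  C <- coreness(net, c(1, 1) / sqrt(2))

  # zero fraction leaves the multiplex untouched
  res <- attack_config(link_fraction = 0, seed = 1) |>
    (\(cfg) attack_multiplex(net, C, cfg))()
  expect_equal(res$attacked_multiplex$W, net$W)
  expect_equal(nrow(res$attacked_pairs), 0)

  # zero reduction changes no weight (renormalization is idempotent)
  res <- attack_multiplex(net, C,
                          attack_config(link_fraction = 0.3, reduction = 0,
                                        seed = 2))
  expect_equal(res$attacked_multiplex$W, net$W, tolerance = 1e-12)
  expect_gt(nrow(res$attacked_pairs), 0)

  # replay: every attacked pair is reduced by exactly (1 - R) in every
  # layer before renormalization, other pairs untouched
  cfg <- attack_config(link_fraction = 0.25, reduction = 0.75, seed = 3)
  res <- attack_multiplex(net, C, cfg, renormalize = FALSE)
  P <- sum(apply(net$W, c(1, 2), max)[upper.tri(net$W[, , 1])] > 0)
  L <- floor(0.25 * P + 0.5)
  expect_equal(nrow(res$attacked_pairs), L)
  expect_equal(nrow(unique(as.data.frame(res$attacked_pairs))), L)
  hit <- matrix(FALSE, 10, 10)
  hit[res$attacked_pairs] <- TRUE
  hit <- hit | t(hit)
  for (m in 1:2) {
    expect_equal(res$attacked_multiplex$W[, , m][hit],
                 net$W[, , m][hit] * 0.25)
    expect_equal(res$attacked_multiplex$W[, , m][!hit],
                 net$W[, , m][!hit])
  }

  # bit-reproducible for a fixed seed
  res2 <- attack_multiplex(net, C, cfg, renormalize = FALSE)
  expect_identical(res$attacked_pairs, res2$attacked_pairs)
  expect_identical(res$attacked_multiplex$W, res2$attacked_multiplex$W)

  # total weight strictly decreases before renormalization when R > 0
  expect_lt(sum(res$attacked_multiplex$W), sum(net$W))
})

test_that("unreachable attack quotas are capped with a warning", {
  set.seed(201)
  net <- rand_multiplex(6, 1)
  # only 3 nodes have positive probability -> 3 samplable pairs
  C <- c(1, 1, 1, 0, 0, 0) * 0.8
  expect_warning(
    res <- attack_multiplex(net, C,
                            attack_config(link_fraction = 1, seed = 4)),
    "reachable")
  expect_equal(nrow(res$attacked_pairs), 3)
  expect_true(all(res$attacked_pairs <= 3))
})

test_that("core-targeted attacks hit high-coreness nodes harder", {
  diffs <- numeric(8)
  for (s in 1:8) {
    cfg <- synthetic_config(n_nodes = 40, n_core = 8, n_hc = 2, n_ad = 2,
                            layer_spec = c(l1 = "fmri_like",
                                           l2 = "dwi_like"),
                            affected_layers = "l1", seed = 400 + s)
    set.seed(400 + s)
    net <- generate_hc_subject(cfg)
    cv <- c(1, 1) / sqrt(2)
    C0 <- coreness(net, cv)
    top <- order(-C0$coreness)[1:4]  # top decile of 40 nodes
    acfg_core <- attack_config(0.5, 0.9, "core", seed = 500 + s)
    acfg_peri <- attack_config(0.5, 0.9, "periphery", seed = 500 + s)
    Cc <- coreness(attack_multiplex(net, C0, acfg_core)$attacked_multiplex,
                   cv)$coreness
    Cp <- coreness(attack_multiplex(net, C0, acfg_peri)$attacked_multiplex,
                   cv)$coreness
    diffs[s] <- mean(Cp[top]) - mean(Cc[top])
  }
  # paired over seeds: core mode degrades the top-decile nodes more
  expect_lt(stats::t.test(diffs, alternative = "greater")$p.value, 0.05)
  expect_gt(mean(diffs), 0)
})

test_that("disruption sweep enumerates subjects, replicates and fractions", {
  set.seed(211)
  cohort <- lapply(1:5, function(i) rand_multiplex(12, 2))
  cv <- c(0.6, 0.8)
  tab <- disruption_sweep(cohort, cv, fractions = 0.2, n_rand = 3, seed = 6)
  expect_equal(nrow(tab), 15)
  expect_equal(sort(unique(tab$subject)), 1:5)
  expect_equal(sort(unique(tab$replicate)), 1:3)

  # zero fraction performs no attack: every kappa equals the subject's
  # baseline disruption against the cohort mean, and those average to 0
  # exactly (the regression is linear in the subject profiles)
  cfg <- small_config(seed = 212)
  set.seed(212)
  hc <- lapply(1:8, function(i) generate_hc_subject(cfg))
  cv <- rep(1, 9) / 3
  tab0 <- disruption_sweep(hc, cv, fractions = 0, n_rand = 1, seed = 7)
  base <- sapply(hc, function(net) coreness(net, cv)$coreness)
  ref <- rowMeans(base)
  direct <- apply(base, 2, function(v) individual_disruption(v, ref)$kappa)
  expect_equal(tab0$kappa, unname(direct))
  expect_equal(mean(tab0$kappa), 0, tolerance = 1e-10)
})
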