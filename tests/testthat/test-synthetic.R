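test_that("generated subjects honor the multiplex construction contract", {
  cfg <- small_config()
  set.seed(251)
  net <- generate_hc_subject(cfg)
  expect_s3_class(net, "multiplex")
  expect_equal(n_nodes(net), 30)
  expect_equal(n_layers(net), 9)
  expect_true(all(net$W >= 0 & net$W <= 1))
  for (m in seq_len(9)) {
    expect_equal(net$W[, , m], t(net$W[, , m]))
    expect_true(all(diag(net$W[, , m]) == 0))
  }
  # determinism under a fixed seed
  set.seed(252); n1 <- generate_hc_subject(cfg)
  set.seed(252); n2 <- generate_hc_subject(cfg)
  expect_identical(n1$W, n2$W)
})

test_that("the planted core carries higher coreness than the periphery", {
  gaps <- numeric(5)
  for (s in 1:5) {
    cfg <- small_config(seed = 260 + s)
    set.seed(260 + s)
    cv <- rep(1, 9) / 3
    Cs <- replicate(4, coreness(generate_hc_subject(cfg), cv)$coreness)
    Cbar <- rowMeans(Cs)
    core <- seq_len(cfg$n_core)
    gaps[s] <- mean(Cbar[core]) - mean(Cbar[-core])
  }
  expect_true(all(gaps > 0.1))
})

test_that("patient generation applies a severity-scaled core attack", {
  cfg <- small_config(seed = NULL)
  set.seed(271)
  res0 <- generate_ad_subject(cfg, 0)
  expect_equal(nrow(res0$ground_truth$attacked_pairs), 0)

  set.seed(272)
  res <- generate_ad_subject(cfg, 1)
  expect_gt(nrow(res$ground_truth$attacked_pairs), 0)
  expect_equal(res$ground_truth$severity, 1)
  expect_true(all(res$net$W >= 0 & res$net$W <= 1))

  # attacked pairs are incident to the planted core above chance
  core <- seq_len(cfg$n_core)
  pairs <- res$ground_truth$attacked_pairs
  hits <- sum(pairs[, 1] %in% core | pairs[, 2] %in% core)
  # binomial test against uniform pair choice on 30 nodes with 6 core
  p_null <- 1 - choose(30 - 6, 2) / choose(30, 2)
  bt <- stats::binom.test(hits, nrow(pairs), p_null,
                          alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})

test_that("severe patients show negative disruption against the HC mean", {
  share_neg <- numeric(3)
  for (s in 1:3) {
    cfg <- small_config(seed = 280 + s, n_hc = 8)
    set.seed(280 + s)
    cv <- rep(1, 9) / 3
    hc <- replicate(8, coreness(generate_hc_subject(cfg), cv)$coreness)
    ref <- rowMeans(hc)
    kappas <- replicate(10, {
      ad <- generate_ad_subject(cfg, 1)
      individual_disruption(coreness(ad$net, cv)$coreness, ref)$kappa
    })
    share_neg[s] <- mean(kappas < 0)
  }
  expect_true(all(share_neg >= 0.9))
})

test_that("behavior scores map severity onto the clinical scales", {
  cfg <- synthetic_config(n_hc = 3, behavior_noise_sd = 0)
  set.seed(291)
  tab <- generate_behavior(c(0, 0.5, 1), cfg)
  ad <- tab[tab$group == "ad", ]
  expect_equal(ad$mmse, c(30, 24, 18))
  expect_true(all(tab$mmse >= 18 & tab$mmse <= 30))
  expect_true(all(tab$recall_immediate >= 0 & tab$recall_immediate <= 48))
  expect_true(all(tab$recall_free >= 0 & tab$recall_free <= 48))
  expect_equal(nrow(tab), 6)
  # controls near ceiling
  expect_true(all(tab$mmse[tab$group == "hc"] >= 28))
})

test_that("cohort writing round-trips through the interchange layout", {
  cfg <- synthetic_config(n_nodes = 20, n_core = 5, n_hc = 4, n_ad = 3,
                          layer_spec = c(alpha1 = "meg_like",
                                         fmri = "fmri_like",
                                         dwi = "dwi_like"),
                          affected_layers = "dwi", seed = 301)
  dir <- withr::local_tempdir()
  study <- generate_cohort(cfg, dir = dir)
  expect_length(study$subjects, 7)
  expect_equal(as.integer(table(study$group)), c(4, 3))

  manifests <- list.files(dir, pattern = "_manifest\\.json$")
  expect_length(manifests, 7)

  back <- read_cohort(dir)
  expect_setequal(names(back$subjects), names(study$subjects))
  for (id in names(study$subjects)) {
    expect_equal(back$subjects[[id]]$W, study$subjects[[id]]$W,
                 tolerance = 1e-12)
    expect_identical(back$subjects[[id]]$layers, study$subjects[[id]]$layers)
  }
  # ground truth covers every patient
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_length(gt$severities, 3)
  expect_length(gt$attacked_pairs, 3)
  expect_equal(sort(gt$core), 1:5)
  # behavior table re-read intact
  expect_equal(back$behavior$subject_id, study$behavior$subject_id)

  # two cohorts from the same seed are identical
  study2 <- generate_cohort(cfg)
  expect_identical(study2$subjects[[1]]$W, study$subjects[[1]]$W)
  expect_identical(study2$behavior, study$behavior)
})
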