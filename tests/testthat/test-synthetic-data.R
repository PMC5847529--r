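test_that("simulation is deterministic given config and seed", {
  cfg <- sim_preset("default", n_chroms = 2, n_capture_regions = 4)
  s1 <- simulate_chic(cfg, seed = 5)
  s2 <- simulate_chic(cfg, seed = 5)
  expect_identical(s1$fragment_map, s2$fragment_map)
  expect_identical(s1$pair_counts, s2$pair_counts)
  expect_identical(s1$trans_counts, s2$trans_counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_chic(cfg, seed = 6)
  expect_false(identical(s1$pair_counts, s3$pair_counts))
})

test_that("fragment sizes follow the configured geometric mean", {
  cfg <- sim_preset("default", n_chroms = 1, chrom_length = 1e7,
                    mean_frag_size = 4000, n_capture_regions = 0)
  counts <- vapply(1:5, function(s) {
    nrow(simulate_fragment_map(cfg, s)$fragment_map)
  }, numeric(1))
  # expectation: chrom_length / mean_frag_size = 2500 fragments
  expect_true(all(abs(counts - 2500) / 2500 < 0.1))
  # no captured fragments without capture regions
  fm <- simulate_fragment_map(cfg, 1)$fragment_map
  expect_false(any(fm$captured))
})

test_that("fragment maps tile chromosomes and regions hold one SNP each", {
  cfg <- sim_preset("default")
  geno <- simulate_fragment_map(cfg, 3)
  fm <- geno$fragment_map
  for (ch in unique(fm$chrom)) {
    f <- fm[fm$chrom == ch, ]
    expect_equal(f$start[1], 0)
    expect_equal(f$end[nrow(f)], cfg$chrom_length)
    expect_true(all(f$start[-1] == f$end[-nrow(f)]))
  }
  expect_equal(nrow(geno$risk_snps), cfg$n_capture_regions)
  expect_true(all(geno$loci$is_risk))
})

test_that("interactability mixture has the configured noise fraction", {
  cfg <- sim_preset("default", n_capture_regions = 16,
                    chrom_length = 5e6, noise_fraction = 0.2)
  fracs <- vapply(1:6, function(s) {
    sim <- simulate_fragment_map(cfg, s)
    mean(simulate_interactability(sim$fragment_map, cfg,
                                  s)$interactability$is_noise)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.2), 0.05)
})

test_that("replicate scales shift mean trans counts proportionally", {
  cfg <- sim_preset("default", replicate_scales = c(r1 = 1, r2 = 2))
  geno <- simulate_fragment_map(cfg, 4)
  inter <- simulate_interactability(geno$fragment_map, cfg, 4)
  signal <- inter$interactability$frag_id[!inter$interactability$is_noise]
  tc <- inter$trans_counts[inter$trans_counts$frag_id %in% signal, ]
  m1 <- mean(tc$n_trans[tc$replicate_id == "r1"])
  m2 <- mean(tc$n_trans[tc$replicate_id == "r2"])
  expect_lt(abs(m2 / m1 - 2), 0.2)
})

test_that("pair-count means follow the power-law decay construction", {
  cfg <- sim_preset("null", decay_exponent = 1)
  sim <- simulate_chic(cfg, seed = 11)
  # empirical mean of unplanted counts tracks mu over distance bins
  unplanted <- sim$truth
  obs <- sim$pair_counts |>
    dplyr::group_by(frag_lo, frag_hi) |>
    dplyr::summarise(y = sum(count), .groups = "drop")
  joined <- dplyr::left_join(unplanted, obs, by = c("frag_lo", "frag_hi"))
  joined$y[is.na(joined$y)] <- 0
  joined$decile <- dplyr::ntile(joined$distance, 10)
  agg <- joined |>
    dplyr::group_by(decile) |>
    dplyr::summarise(obs = mean(y), exp = mean(mu_combined))
  # within sampling error per decile (thousands of pairs each)
  expect_true(all(abs(agg$obs - agg$exp) / pmax(agg$exp, 0.01) < 0.15))
  # decay: expected counts fall steeply with distance for alpha = 1
  expect_lt(agg$exp[10], agg$exp[1] / 4)
})

test_that("planted pairs get the configured fold enrichment", {
  cfg <- sim_preset("power")
  sim <- simulate_chic(cfg, seed = 12)
  planted <- dplyr::filter(sim$truth, enrichment > 1)
  expect_equal(nrow(planted), cfg$n_planted_c2c + cfg$n_planted_wc)
  expect_true(all(planted$enrichment == 8))
  expect_true(all(planted$detectable))
  expect_true(all(planted$mu_combined >= 8 * cfg$planted_min_mean))
  expect_setequal(unique(planted$pair_class),
                  c("capture_to_cis", "within_capture"))
  # the planted keys exist in the generated candidate space
  all_keys <- pair_key(sim$truth$frag_lo, sim$truth$frag_hi)
  expect_true(all(pair_key(planted$frag_lo, planted$frag_hi) %in%
                    all_keys))
})

test_that("trans-count histogram is bimodal under the default mixture", {
  cfg <- sim_preset("default")
  sim <- simulate_chic(cfg, seed = 13)
  x <- sim$trans_counts$n_trans[sim$trans_counts$replicate_id == "rep1"]
  t_hat <- select_truncation_point(x)
  expect_gt(t_hat, 0)  # a valley exists
  # degenerate mixture: no noise -> unimodal, t = 0 path
  cfg0 <- sim_preset("default", noise_fraction = 0)
  sim0 <- simulate_chic(cfg0, seed = 13)
  x0 <- sim0$trans_counts$n_trans[sim0$trans_counts$replicate_id ==
                                    "rep1"]
  expect_warning(t0 <- select_truncation_point(x0), "unimodal|adjacent")
  expect_equal(t0, 0L)
})

test_that("truth evaluation computes FDP and sensitivity arithmetic", {
  truth <- tibble::tibble(
    frag_lo = 1:12, frag_hi = 21:32,
    pair_class = "capture_to_cis", distance = 1e5,
    enrichment = c(rep(8, 10), 1, 1),
    detectable = TRUE, mu_combined = 50
  )
  # 8 of 10 planted called plus one spurious call
  calls <- tibble::tibble(frag_lo = c(1:8, 11), frag_hi = c(21:28, 31),
                          significant = TRUE)
  out <- truth_evaluation(calls, truth)
  expect_equal(out$fdp, 1 / 9)
  expect_equal(out$sensitivity, 0.8)
  # no calls
  none <- truth_evaluation(calls[0, ], truth)
  expect_equal(none$fdp, 0)
  expect_equal(none$sensitivity, 0)
  # perfect recovery
  perfect <- truth_evaluation(
    tibble::tibble(frag_lo = 1:10, frag_hi = 21:30, significant = TRUE),
    truth)
  expect_equal(perfect$fdp, 0)
  expect_equal(perfect$sensitivity, 1)
})

test_that("zero base rate silences the pipeline end to end", {
  cfg <- sim_preset("null", base_rate = 1e-9)
  sim <- simulate_chic(cfg, seed = 14)
  expect_equal(nrow(sim$pair_counts), 0)
})
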