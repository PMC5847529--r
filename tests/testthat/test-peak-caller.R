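test_that("candidate enumeration covers the distance window with zeros", {
  # 1 kept bait in a 100-fragment chromosome, sparse observed counts
  fm <- tiled_fragment_map("chr1", 100, 5e4)
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 5e4,
                            region_id = "R")
  fm <- mark_captured(fm, regions)
  snps <- tibble::tibble(rsid = "rs1", chrom = "chr1", pos = 100)
  loci <- define_loci(regions, snps)
  nt <- tibble::tibble(frag_id = 1L,
                       replicate_id = c("rep1", "rep2"),
                       n_trans = c(100L, 120L))
  obs <- tibble::tibble(frag_lo = 1L, frag_hi = 2:11,
                        replicate_id = "rep1", count = 3L)
  cand <- enumerate_candidate_pairs(fm, 1L, obs, nt, loci,
                                    min_dist = 1e4, max_dist = 5e6)
  # partners at >= 10 kb midpoint distance: fragment 2 is 50 kb away, all
  # 99 others are in range
  expect_equal(nrow(cand), 99)
  expect_equal(sum(cand$y > 0), 10)
  expect_equal(sum(cand$y == 0), 89)
  expect_true(all(cand$pair_class == "capture_to_cis"))
  expect_true(all(cand$distance >= 1e4 & cand$distance <= 5e6))
  expect_equal(unique(cand$locus_id), "locus_1")
  expect_equal(cand$ln_nt_a_rep1, rep(log(100), 99))
  # a partner closer than min_dist is not a candidate
  expect_false(any(cand$distance < 1e4))
})

test_that("equal-count binning respects ties and minimum bin size", {
  cand <- tibble::tibble(distance = seq_len(300) * 1e3)
  b <- assign_distance_bins(cand, n_bins = 100, min_bin_pairs = 3)
  expect_equal(length(unique(b$bin_id)), 100)
  expect_true(all(table(b$bin_id) == 3))
  # all distances identical -> one bin
  same <- tibble::tibble(distance = rep(5e4, 50))
  expect_equal(unique(assign_distance_bins(same, 100, 3)$bin_id), 1L)
  # too few candidates for the requested bins -> single bin
  few <- tibble::tibble(distance = seq_len(150) * 1e3)
  expect_equal(unique(assign_distance_bins(few, 100, 200)$bin_id), 1L)
  # bins are distance-ordered: larger bin id, larger distances
  agg <- dplyr::summarise(dplyr::group_by(b, bin_id),
                          lo = min(distance), hi = max(distance))
  agg <- dplyr::arrange(agg, bin_id)
  expect_true(all(diff(agg$lo) > 0))
})

test_that("background regression recovers known coefficients", {
  # simulate from the exact capture_to_cis model
  withr::with_seed(21, {
    n <- 5000
    ln_nt_1 <- log(rnbinom(n, mu = 300, size = 5) + 1)
    ln_nt_2 <- log(rnbinom(n, mu = 360, size = 5) + 1)
    ln_d <- log(runif(n, 1e4, 1e5))
    beta <- c(intercept = 8, nt1 = 0.5, nt2 = 0.4, d = -1)
    mu <- exp(beta[1] + beta[2] * ln_nt_1 + beta[3] * ln_nt_2 +
                beta[4] * ln_d)
    y <- rnbinom(n, mu = mu, size = 6)
  })
  cand <- tibble::tibble(y = y, ln_d = ln_d,
                         ln_nt_a_rep1 = ln_nt_1, ln_nt_a_rep2 = ln_nt_2)
  fit <- fit_background_model(cand, "capture_to_cis")
  se <- summary(fit$model)$coefficients[, "Std. Error"]
  est <- fit$coefficients
  truth <- c(8, -1, 0.5, 0.4)  # intercept, ln_d, nt rep1, nt rep2
  expect_true(all(abs(est - truth) < 3 * se))
  expect_lt(abs(fit$size - 6) / 6, 0.3)
  expect_true(fit$converged)
})

test_that("within-capture model is invariant to fragment order", {
  withr::with_seed(22, {
    n <- 2000
    a1 <- log(rnbinom(n, mu = 200, size = 5) + 1)
    b1 <- log(rnbinom(n, mu = 200, size = 5) + 1)
    a2 <- a1 + rnorm(n, 0, 0.05)
    b2 <- b1 + rnorm(n, 0, 0.05)
    ln_d <- log(runif(n, 1e4, 1e6))
    mu <- exp(2 + 0.3 * (a1 + b1) + 0.05 * a1 * b1 - 0.8 * ln_d + 8)
    y <- rnbinom(n, mu = mu, size = 6)
  })
  cand <- tibble::tibble(y = y, ln_d = ln_d,
                         ln_nt_a_rep1 = a1, ln_nt_b_rep1 = b1,
                         ln_nt_a_rep2 = a2, ln_nt_b_rep2 = b2)
  swapped <- dplyr::rename(cand, ln_nt_a_rep1 = "ln_nt_b_rep1",
                           ln_nt_b_rep1 = "ln_nt_a_rep1",
                           ln_nt_a_rep2 = "ln_nt_b_rep2",
                           ln_nt_b_rep2 = "ln_nt_a_rep2")
  f1 <- fit_background_model(cand, "within_capture")
  f2 <- fit_background_model(swapped, "within_capture")
  expect_equal(f1$mu_hat, f2$mu_hat, tolerance = 1e-8)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("constant covariates collapse to a mean fit near ln(lambda)", {
  withr::with_seed(23, y <- rpois(4000, 5))
  cand <- tibble::tibble(y = y, ln_d = 10,
                         ln_nt_a_rep1 = 4, ln_nt_a_rep2 = 4)
  fit <- suppressWarnings(suppressMessages(
    fit_background_model(cand, "capture_to_cis")))
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(5),
               tolerance = 0.05)
  expect_gt(fit$size, 50)
  # an all-zero bin yields p = 1 everywhere
  zero <- tibble::tibble(y = rep(0L, 300), ln_d = log(seq_len(300) * 1e3),
                         ln_nt_a_rep1 = 4, ln_nt_a_rep2 = 4)
  fz <- fit_background_model(zero, "capture_to_cis")
  expect_true(all(fz$mu_hat < 1e-6))
  expect_true(all(pair_pvalue(zero$y, pmax(fz$mu_hat, 1e-12),
                              fz$size) == 1))
})

test_that("upper-tail p-values match closed forms and brute force", {
  expect_equal(pair_pvalue(0, 5, 2), 1)
  # Poisson limit mu = 2: P(Y >= 3) = 1 - 5 exp(-2)
  expect_equal(pair_pvalue(3, 2, 1e9), 1 - 5 * exp(-2), tolerance = 1e-6)
  # geometric (size 1, mu 1): P(Y >= 2) = (1/2)^2
  expect_equal(pair_pvalue(2, 1, 1), 0.25, tolerance = 1e-12)
  # brute-force mass summation across a parameter grid
  for (mu in c(0.1, 1, 7, 40)) {
    for (size in c(0.5, 2, 20)) {
      for (y in c(1, 3, 17, 120)) {
        expect_lt(abs(pair_pvalue(y, mu, size) -
                        nb_tail_oracle(y, mu, size)), 1e-10)
      }
    }
  }
})

test_that("BH adjustment matches the hand formula within groups", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_fdr(0.037), 0.037)
  expect_equal(adjust_fdr(c(1, 1)), c(1, 1))
  # grouping is respected: each group adjusted independently
  p <- c(0.01, 0.02, 0.01, 0.02)
  g <- c("a", "a", "b", "b")
  expect_equal(adjust_fdr(p, g), c(0.02, 0.02, 0.02, 0.02))
  expect_true(all(adjust_fdr(runif(50)) >= runif(0)))
})

test_that("significance needs both the FDR threshold and distance window", {
  tested <- tibble::tibble(
    locus_id = "L", p_adj = c(0.009, 0.009, 0.011),
    distance = c(1e5, 8e3, 1e5)
  )
  out <- call_peaks(tested, alpha = 0.01, min_dist = 1e4, max_dist = 5e6)
  expect_equal(sum(out$significant), 1)
  expect_true(out$significant[out$p_adj < 0.01 & out$distance == 1e5])
})

test_that("peak calls are symmetric in fragment order within pairs", {
  cfg <- sim_preset("default", n_chroms = 2, n_capture_regions = 4)
  sim <- simulate_chic(cfg, seed = 9)
  fits <- fit_interactability_filters(sim$trans_counts)
  filt <- filter_fragments(sim$trans_counts, fits)
  cand <- enumerate_candidate_pairs(sim$fragment_map,
                                    filt$frag_id[filt$kept],
                                    sim$pair_counts, sim$trans_counts,
                                    sim$loci)
  wc <- dplyr::filter(cand, pair_class == "within_capture")
  # swapping the within-capture covariate roles leaves the fit unchanged
  swapped <- dplyr::rename(wc, ln_nt_a_rep1 = "ln_nt_b_rep1",
                           ln_nt_b_rep1 = "ln_nt_a_rep1",
                           ln_nt_a_rep2 = "ln_nt_b_rep2",
                           ln_nt_b_rep2 = "ln_nt_a_rep2")
  r1 <- suppressWarnings(test_candidate_pairs(wc, min_bin_pairs = 100))
  r2 <- suppressWarnings(test_candidate_pairs(swapped,
                                              min_bin_pairs = 100))
  expect_equal(r1$peaks$p, r2$peaks$p, tolerance = 1e-8)
})
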