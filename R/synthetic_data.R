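#' Configuration for the CHi-C simulator
#'
#' Defines the generative model used for false-discovery and power
#' evaluation. The simulator mirrors the assumptions of the peak caller:
#' fragments from a geometric digestion process, a bimodal interactability
#' mixture over captured fragments (a minority of failed, near-silent
#' baits plus working baits with overdispersed trans counts), power-law
#' distance decay of cis contact rates, per-replicate library-size
#' multipliers, negative-binomial counting noise, and optional planted
#' enriched pairs.
#'
#' Defaults describe a desk-scale capture design: 4 chromosomes of 2.5 Mb,
#' 4 kb mean fragment size, 8 capture regions of 100 kb (about 200
#' captured fragments), 20% failed baits (the study this emulates excluded
#' 8.6-30% of baits per library), working-bait trans counts NB(300, 5)
#' against Poisson(3) noise, contact decay exponent 1, and moderate count
#' overdispersion (size 6).
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param mean_frag_size Mean restriction-fragment size in bp.
#' @param n_capture_regions Total capture regions (spread round-robin
#'   across chromosomes).
#' @param region_width Capture-region width in bp.
#' @param noise_fraction Probability that a captured fragment is a failed
#'   bait.
#' @param noise_trans_mean Poisson mean of failed-bait trans counts.
#' @param signal_trans_mu,signal_trans_size NB parameters of working-bait
#'   trans counts (per unit replicate scale).
#' @param decay_exponent Power-law exponent `alpha` of distance decay.
#' @param base_rate Baseline cis contact rate `k`:
#'   `mu_ij = k * scale_r * B_i * B_j * D^-alpha * E_ij`.
#' @param count_dispersion NB size of pair-count noise.
#' @param replicate_scales Named or unnamed numeric vector of per-replicate
#'   library-scale multipliers (names default to `rep1`, `rep2`, ...).
#' @param n_planted_c2c,n_planted_wc Planted enriched pairs per class
#'   (drawn at random among eligible pairs).
#' @param planted_enrichment Fold enrichment `E` of planted pairs.
#' @param planted_min_mean Minimum combined background mean for a pair to
#'   be eligible for planting.
#' @param planted_pairs Optional explicit pair selector: a tibble with
#'   `frag_lo`, `frag_hi` and optionally `enrichment` columns. When given,
#'   exactly these pairs are planted and the random selection is skipped
#'   (useful for giving several simulated cell lines a shared peak set).
#' @param min_dist,max_dist Candidate distance window in bp.
#' @return A `chic_sim_config` list.
#' @export
sim_config <- function(n_chroms = 4, chrom_length = 2.5e6,
                       mean_frag_size = 4000, n_capture_regions = 8,
                       region_width = 1e5, noise_fraction = 0.2,
                       noise_trans_mean = 3, signal_trans_mu = 300,
                       signal_trans_size = 5, decay_exponent = 1,
                       base_rate = 4e5, count_dispersion = 6,
                       replicate_scales = c(rep1 = 1.0, rep2 = 1.2),
                       n_planted_c2c = 15, n_planted_wc = 5,
                       planted_enrichment = 8, planted_min_mean = 20,
                       planted_pairs = NULL,
                       min_dist = 1e4, max_dist = 5e6) {
  if (is.null(names(replicate_scales))) {
    names(replicate_scales) <- paste0("rep", seq_along(replicate_scales))
  }
  cfg <- list(
    n_chroms = n_chroms, chrom_length = chrom_length,
    mean_frag_size = mean_frag_size,
    n_capture_regions = n_capture_regions, region_width = region_width,
    noise_fraction = noise_fraction, noise_trans_mean = noise_trans_mean,
    signal_trans_mu = signal_trans_mu,
    signal_trans_size = signal_trans_size,
    decay_exponent = decay_exponent, base_rate = base_rate,
    count_dispersion = count_dispersion,
    replicate_scales = replicate_scales,
    n_planted_c2c = n_planted_c2c, n_planted_wc = n_planted_wc,
    planted_enrichment = planted_enrichment,
    planted_min_mean = planted_min_mean,
    planted_pairs = planted_pairs,
    min_dist = min_dist, max_dist = max_dist
  )
  stopifnot(cfg$noise_fraction >= 0, cfg$noise_fraction <= 1,
            cfg$decay_exponent > 0, cfg$base_rate > 0,
            cfg$planted_enrichment >= 1, all(cfg$replicate_scales > 0))
  structure(cfg, class = "chic_sim_config")
}

#' Preset simulator configurations
#'
#' * `"default"` — the standard benchmark: planted peaks in both ligation
#'   classes at 8-fold enrichment.
#' * `"null"` — no planted peaks; used for false-discovery calibration.
#' * `"power"` — planted peaks at 8-fold enrichment over background means
#'   of at least 20; used for sensitivity evaluation.
#'
#' @param preset One of `"default"`, `"null"`, `"power"`.
#' @param ... Overrides passed to [sim_config()].
#' @return A `chic_sim_config`.
#' @export
sim_preset <- function(preset = c("default", "null", "power"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    default = list(),
    null = list(n_planted_c2c = 0, n_planted_wc = 0),
    power = list(n_planted_c2c = 15, n_planted_wc = 5,
                 planted_enrichment = 8, planted_min_mean = 20)
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Deterministic per-stage sub-seed, kept below 2^31.
sub_seed <- function(seed, stage) {
  (seed * 7 + stage * 104729) %% 2147483647
}

#' Simulate a fragment map with capture design and risk SNPs
#'
#' Fragment boundaries come from geometric inter-cut distances with mean
#' `mean_frag_size`; capture regions are placed uniformly without overlap
#' (round-robin across chromosomes) with one risk SNP at each region
#' midpoint.
#'
#' @param config A `chic_sim_config`.
#' @param seed Integer seed.
#' @return List: `fragment_map`, `capture_regions`, `risk_snps`, `loci`.
#' @export
simulate_fragment_map <- function(config, seed) {
  withr::with_seed(sub_seed(seed, 1), {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    frags <- lapply(chroms, function(ch) {
      gaps <- integer(0)
      total <- 0
      while (total < config$chrom_length) {
        g <- rgeom(256, prob = 1 / config$mean_frag_size) + 1L
        gaps <- c(gaps, g)
        total <- sum(as.numeric(gaps))
      }
      bounds <- c(0, cumsum(as.numeric(gaps)))
      bounds <- bounds[bounds < config$chrom_length]
      bounds <- c(bounds, config$chrom_length)
      tibble::tibble(start = bounds[-length(bounds)], end = bounds[-1])
    })
    names(frags) <- chroms
    fragment_map <- new_fragment_map(frags)
    regions <- NULL
    if (config$n_capture_regions > 0) {
      per_chrom <- split(seq_len(config$n_capture_regions),
                         rep(chroms,
                             length.out = config$n_capture_regions))
      regions <- purrr::imap(per_chrom, function(ids, ch) {
        n <- length(ids)
        if (n * config$region_width > config$chrom_length) {
          stop("capture regions cannot be placed without overlap")
        }
        # sample starts until non-overlapping (slack makes this fast)
        for (attempt in 1:200) {
          starts <- sort(sample.int(
            config$chrom_length - config$region_width, n))
          if (n == 1 ||
              all(diff(starts) >= config$region_width)) break
          if (attempt == 200) {
            stop("capture regions cannot be placed without overlap")
          }
        }
        tibble::tibble(chrom = ch, start = starts,
                       end = starts + config$region_width,
                       region_id = paste0("region_", ids))
      }) |> dplyr::bind_rows()
      fragment_map <- mark_captured(fragment_map, regions)
    } else {
      regions <- tibble::tibble(chrom = character(), start = double(),
                                end = double(), region_id = character())
    }
    risk_snps <- tibble::tibble(
      rsid = paste0("rs", seq_len(nrow(regions))),
      chrom = regions$chrom,
      pos = floor((regions$start + regions$end) / 2) + 1
    )
    loci <- if (nrow(regions) > 0) {
      define_loci(regions, risk_snps, merge_gap = 0)
    } else NULL
    list(fragment_map = fragment_map, capture_regions = regions,
         risk_snps = risk_snps, loci = loci)
  })
}

#' Simulate bimodal interactability and per-replicate trans counts
#'
#' With probability `noise_fraction` a captured fragment is a failed bait:
#' trans counts are Poisson(`noise_trans_mean`) and its contact propensity
#' `B_i` is near zero. Working baits draw a fragment-specific gamma factor
#' `G_i ~ Gamma(size, size)` shared across replicates, so trans counts are
#' Poisson(`scale_r * mu * G_i`) — marginally NB(`scale_r * mu`, size) —
#' and `B_i = G_i` (mean 1 over working baits). Tying `B_i` to the
#' expected trans count makes the caller's interactability covariate
#' genuinely informative.
#'
#' @param fragment_map Fragment map with captured flags.
#' @param config A `chic_sim_config`.
#' @param seed Integer seed.
#' @return List: `interactability` tibble (`frag_id`, `is_noise`, `b`) and
#'   `trans_counts` tibble (`frag_id`, `replicate_id`, `n_trans`).
#' @export
simulate_interactability <- function(fragment_map, config, seed) {
  captured <- fragment_map$frag_id[fragment_map$captured]
  stopifnot(length(captured) > 0)
  reps <- names(config$replicate_scales)
  withr::with_seed(sub_seed(seed, 2), {
    n <- length(captured)
    is_noise <- runif(n) < config$noise_fraction
    g <- rgamma(n, shape = config$signal_trans_size,
                rate = config$signal_trans_size)
    b <- ifelse(is_noise, 0.02, g)
    trans <- purrr::map(reps, function(r) {
      scale_r <- config$replicate_scales[[r]]
      lambda <- ifelse(is_noise, config$noise_trans_mean,
                       scale_r * config$signal_trans_mu * g)
      tibble::tibble(frag_id = captured, replicate_id = r,
                     n_trans = rpois(n, lambda))
    }) |> dplyr::bind_rows()
    list(
      interactability = tibble::tibble(frag_id = captured,
                                       is_noise = is_noise, b = b),
      trans_counts = dplyr::arrange(trans, .data$frag_id,
                                    .data$replicate_id)
    )
  })
}

#' Simulate per-replicate fragment-pair di-tag counts with planted peaks
#'
#' For every pair of a captured fragment with a cis partner within
#' `max_dist`, draws per-replicate counts
#' `NB(k * scale_r * B_i * B_j * D^-alpha * E_ij, size_c)`, with
#' `B_j = 1` for non-captured partners and `E_ij` the planted enrichment
#' (1 for unplanted pairs). Planted pairs are sampled uniformly among
#' pairs of working baits whose combined background mean reaches
#' `planted_min_mean`; a planted pair outside the caller's distance window
#' triggers a warning (undetectable by design).
#'
#' @param fragment_map Fragment map with captured flags.
#' @param interactability Output element of [simulate_interactability()].
#' @param config A `chic_sim_config`.
#' @param seed Integer seed.
#' @return List: `pair_counts` (long tibble of non-zero counts:
#'   `frag_lo`, `frag_hi`, `replicate_id`, `count`, `pair_class`,
#'   `distance`) and `truth` (tibble `frag_lo`, `frag_hi`, `pair_class`,
#'   `distance`, `enrichment`, `detectable`, `mu_combined`).
#' @export
simulate_ditags <- function(fragment_map, interactability, config, seed) {
  fm <- dplyr::arrange(fragment_map, .data$frag_id)
  mid <- floor((fm$start + fm$end) / 2)
  b_vec <- rep(1, nrow(fm))
  noise_vec <- rep(FALSE, nrow(fm))
  idx <- match(interactability$frag_id, fm$frag_id)
  b_vec[idx] <- interactability$b
  noise_vec[idx] <- interactability$is_noise
  cap <- fm$captured
  pairs <- purrr::map(which(cap), function(i) {
    same <- which(fm$chrom == fm$chrom[i])
    d <- abs(mid[same] - mid[i])
    sel <- same[d > 0 & d <= config$max_dist]
    if (length(sel) == 0) return(NULL)
    tibble::tibble(bait = i, partner = sel,
                   distance = abs(mid[sel] - mid[i]))
  }) |> dplyr::bind_rows()
  pairs <- pairs |>
    dplyr::mutate(lo = pmin(.data$bait, .data$partner),
                  hi = pmax(.data$bait, .data$partner)) |>
    dplyr::distinct(.data$lo, .data$hi, .keep_all = TRUE) |>
    dplyr::mutate(
      pair_class = ifelse(cap[.data$lo] & cap[.data$hi],
                          "within_capture", "capture_to_cis"),
      mu_base = config$base_rate * b_vec[.data$lo] * b_vec[.data$hi] *
        .data$distance^(-config$decay_exponent)
    )
  total_scale <- sum(config$replicate_scales)
  pairs$mu_combined <- pairs$mu_base * total_scale
  withr::with_seed(sub_seed(seed, 3), {
    pairs$enrichment <- 1
    if (!is.null(config$planted_pairs)) {
      pp <- config$planted_pairs
      e <- if ("enrichment" %in% names(pp)) pp$enrichment else
        rep(config$planted_enrichment, nrow(pp))
      sel <- match(
        pair_key(pmin(pp$frag_lo, pp$frag_hi),
                 pmax(pp$frag_lo, pp$frag_hi)),
        pair_key(fm$frag_id[pairs$lo], fm$frag_id[pairs$hi])
      )
      if (anyNA(sel)) {
        stop("explicit planted pair outside the candidate pair space")
      }
      pairs$enrichment[sel] <- e
    } else for (cls in c("capture_to_cis", "within_capture")) {
      n_plant <- if (cls == "capture_to_cis") config$n_planted_c2c else
        config$n_planted_wc
      if (n_plant == 0) next
      eligible <- which(
        pairs$pair_class == cls &
          pairs$mu_combined >= config$planted_min_mean &
          pairs$distance >= config$min_dist &
          pairs$distance <= config$max_dist &
          !noise_vec[pairs$lo] & !noise_vec[pairs$hi]
      )
      if (length(eligible) < n_plant) {
        stop("not enough eligible pairs to plant in class ", cls)
      }
      chosen <- eligible[sample.int(length(eligible), n_plant)]
      pairs$enrichment[chosen] <- config$planted_enrichment
    }
    out_of_window <- pairs$enrichment > 1 &
      (pairs$distance < config$min_dist | pairs$distance > config$max_dist)
    if (any(out_of_window)) {
      warning(sum(out_of_window), " planted pair(s) outside the ",
              "detection window (undetectable by design)")
    }
    reps <- names(config$replicate_scales)
    counts <- purrr::map(reps, function(r) {
      mu_r <- pairs$mu_base * config$replicate_scales[[r]] *
        pairs$enrichment
      k <- rnbinom(nrow(pairs), mu = mu_r, size = config$count_dispersion)
      keep <- k > 0
      tibble::tibble(frag_lo = fm$frag_id[pairs$lo[keep]],
                     frag_hi = fm$frag_id[pairs$hi[keep]],
                     replicate_id = r, count = k[keep],
                     pair_class = pairs$pair_class[keep],
                     distance = pairs$distance[keep])
    }) |> dplyr::bind_rows()
  })
  truth <- tibble::tibble(
    frag_lo = fm$frag_id[pairs$lo], frag_hi = fm$frag_id[pairs$hi],
    pair_class = pairs$pair_class, distance = pairs$distance,
    enrichment = pairs$enrichment,
    detectable = pairs$distance >= config$min_dist &
      pairs$distance <= config$max_dist,
    mu_combined = pairs$mu_combined * pairs$enrichment
  )
  list(pair_counts = dplyr::arrange(counts, .data$frag_lo, .data$frag_hi,
                                    .data$replicate_id),
       truth = truth)
}

#' Simulate a complete CHi-C data set
#'
#' Convenience wrapper running [simulate_fragment_map()],
#' [simulate_interactability()] and [simulate_ditags()] with
#' deterministically derived per-stage sub-seeds: identical config and
#' seed give identical tables.
#'
#' @param config A `chic_sim_config` (see [sim_config()], [sim_preset()]).
#' @param seed Integer seed.
#' @return List: `fragment_map`, `capture_regions`, `risk_snps`, `loci`,
#'   `interactability`, `trans_counts`, `pair_counts`, `truth`, `config`,
#'   `seed`.
#' @export
simulate_chic <- function(config = sim_preset("default"), seed = 1) {
  geno <- simulate_fragment_map(config, seed)
  inter <- simulate_interactability(geno$fragment_map, config, seed)
  tags <- simulate_ditags(geno$fragment_map, inter$interactability,
                          config, seed)
  c(geno, inter, tags, list(config = config, seed = seed))
}

#' Evaluate peak calls against simulation truth
#'
#' False-discovery proportion and sensitivity of a called peak set with
#' respect to the planted pairs of a simulation.
#'
#' @param peaks Peak tibble with `frag_lo`, `frag_hi`, `significant`.
#' @param truth Truth tibble from [simulate_ditags()].
#' @return Tibble `n_called`, `n_planted_detectable`, `true_positives`,
#'   `fdp`, `sensitivity`.
#' @export
truth_evaluation <- function(peaks, truth) {
  called <- dplyr::filter(peaks, .data$significant)
  called_keys <- pair_key(called$frag_lo, called$frag_hi)
  planted <- dplyr::filter(truth, .data$enrichment > 1, .data$detectable)
  planted_keys <- pair_key(planted$frag_lo, planted$frag_hi)
  tp <- sum(called_keys %in% planted_keys)
  tibble::tibble(
    n_called = length(called_keys),
    n_planted_detectable = length(planted_keys),
    true_positives = tp,
    fdp = (length(called_keys) - tp) / max(1, length(called_keys)),
    sensitivity = if (length(planted_keys) == 0) 0 else
      tp / length(planted_keys)
  )
}
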