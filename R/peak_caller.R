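#' Enumerate candidate fragment pairs for peak calling
#'
#' For each captured fragment that survived the interactability filter, all
#' cis partner fragments with midpoint distance in `[min_dist, max_dist]`
#' become candidates, including pairs with no observed di-tags (`y = 0`) —
#' the background model is fitted to the full zero-inflated candidate set.
#' Pairs where both fragments are captured (in the same or in two different
#' capture regions within `max_dist`) form the `within_capture` set; pairs
#' of a captured fragment with a non-captured cis fragment form the
#' `capture_to_cis` set. The two sets are analysed separately. Pairs
#' touching an excluded captured fragment are dropped.
#'
#' Covariates are attached per replicate: `ln_nt_a_<rep>` / `ln_nt_b_<rep>`
#' are the natural logs of the trans totals of the lower/higher fragment
#' (bait only, for `capture_to_cis`). Kept fragments with a zero trans
#' count in any replicate are excluded with a warning (log undefined).
#'
#' @param fragment_map Fragment map with `captured`/`region_id` set.
#' @param kept_fragments Integer vector of captured fragment ids that
#'   passed [filter_fragments()].
#' @param pair_counts Pair-count tibble (long, per replicate; see
#'   [aggregate_pair_counts()] or [simulate_chic()]).
#' @param trans_counts Tibble `frag_id`, `replicate_id`, `n_trans`.
#' @param loci Locus tibble from [define_loci()]; candidates are labelled
#'   with the locus of their (lower) captured fragment.
#' @param min_dist,max_dist Distance window in bp; defaults 1e4 and 5e6.
#' @return Candidate tibble: `frag_lo`, `frag_hi`, `pair_class`, `locus_id`,
#'   `distance`, `ln_d`, `y` (summed over replicates), per-replicate
#'   covariate columns.
#' @export
enumerate_candidate_pairs <- function(fragment_map, kept_fragments,
                                      pair_counts, trans_counts, loci,
                                      min_dist = 1e4, max_dist = 5e6) {
  reps <- sort(unique(trans_counts$replicate_id))
  nt <- trans_counts |>
    dplyr::filter(.data$frag_id %in% kept_fragments) |>
    tidyr::pivot_wider(id_cols = "frag_id", names_from = "replicate_id",
                       values_from = "n_trans", values_fill = 0L)
  zero_nt <- nt$frag_id[apply(as.matrix(nt[reps]) == 0, 1, any)]
  if (length(zero_nt) > 0) {
    warning(length(zero_nt),
            " kept fragment(s) with a zero trans count excluded ",
            "(log interactability undefined)")
    kept_fragments <- setdiff(kept_fragments, zero_nt)
  }
  fm <- dplyr::arrange(fragment_map, .data$frag_id)
  mid <- floor((fm$start + fm$end) / 2)
  keep_set <- fm$frag_id %in% kept_fragments
  cand <- purrr::map(which(keep_set), function(i) {
    same <- which(fm$chrom == fm$chrom[i])
    d <- abs(mid[same] - mid[i])
    sel <- same[d >= min_dist & d <= max_dist & same != i]
    if (length(sel) == 0) return(NULL)
    tibble::tibble(bait = fm$frag_id[i], partner = fm$frag_id[sel],
                   distance = abs(mid[sel] - mid[i]),
                   partner_captured = fm$captured[sel],
                   partner_kept = keep_set[sel])
  })
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0) {
    return(empty_candidates(reps))
  }
  # drop pairs touching an excluded captured fragment; classify the rest
  cand <- cand |>
    dplyr::filter(!(.data$partner_captured & !.data$partner_kept)) |>
    dplyr::mutate(
      pair_class = ifelse(.data$partner_captured,
                          "within_capture", "capture_to_cis"),
      frag_lo = pmin(.data$bait, .data$partner),
      frag_hi = pmax(.data$bait, .data$partner)
    )
  # within-capture pairs are enumerated once from each end; deduplicate
  cand <- dplyr::distinct(cand, .data$frag_lo, .data$frag_hi,
                          .keep_all = TRUE)
  # observed counts, summed over replicates (combined response)
  if (nrow(pair_counts) > 0) {
    obs <- pair_counts |>
      dplyr::group_by(.data$frag_lo, .data$frag_hi) |>
      dplyr::summarise(y = sum(.data$count), .groups = "drop")
    cand <- dplyr::left_join(cand, obs, by = c("frag_lo", "frag_hi"))
  } else {
    cand$y <- 0L
  }
  cand$y <- as.integer(dplyr::coalesce(cand$y, 0L))
  # locus of the captured anchor (lower captured fragment for within_capture)
  rl <- region_locus_map(loci)
  frag_locus <- tibble::tibble(
    frag_id = fm$frag_id,
    locus_id = rl$locus_id[match(fm$region_id, rl$region_id)]
  )
  anchor <- ifelse(cand$pair_class == "within_capture", cand$frag_lo,
                   cand$bait)
  cand$locus_id <- frag_locus$locus_id[match(anchor, frag_locus$frag_id)]
  # per-replicate log interactability covariates
  for (r in reps) {
    nt_r <- setNames(nt[[r]], nt$frag_id)
    ln_lo <- log(nt_r[as.character(cand$frag_lo)])
    ln_hi <- log(nt_r[as.character(cand$frag_hi)])
    bait_is_lo <- cand$bait == cand$frag_lo
    cand[[paste0("ln_nt_a_", r)]] <- ifelse(
      cand$pair_class == "within_capture", ln_lo,
      ifelse(bait_is_lo, ln_lo, ln_hi))
    cand[[paste0("ln_nt_b_", r)]] <- ifelse(
      cand$pair_class == "within_capture", ln_hi, NA_real_)
  }
  cand |>
    dplyr::mutate(ln_d = log(.data$distance)) |>
    dplyr::select("frag_lo", "frag_hi", "pair_class", "locus_id",
                  "distance", "ln_d", "y",
                  dplyr::starts_with("ln_nt_")) |>
    dplyr::arrange(.data$pair_class, .data$frag_lo, .data$frag_hi)
}

empty_candidates <- function(reps) {
  out <- tibble::tibble(frag_lo = integer(), frag_hi = integer(),
                        pair_class = character(), locus_id = character(),
                        distance = double(), ln_d = double(), y = integer())
  for (r in reps) {
    out[[paste0("ln_nt_a_", r)]] <- double()
    out[[paste0("ln_nt_b_", r)]] <- double()
  }
  out
}

#' Assign equal-count distance bins
#'
#' Splits candidates of one analysis class into quantile bins of the
#' distance distribution (default percentiles), so that each background
#' model sees pairs of comparable genomic separation — the binning
#' approximates local smoothing of the distance decay. Equal distances stay
#' in one bin; bins smaller than `min_bin_pairs` are merged with their
#' nearest neighbour. With fewer than `n_bins * min_bin_pairs` candidates
#' the bin count is reduced to `floor(n / min_bin_pairs)` (minimum 1).
#'
#' @param candidates Candidate tibble (one `pair_class`).
#' @param n_bins Target number of bins; default 100.
#' @param min_bin_pairs Minimum pairs per bin; default 200.
#' @return The input with an integer `bin_id` column.
#' @export
assign_distance_bins <- function(candidates, n_bins = 100,
                                 min_bin_pairs = 200) {
  stopifnot(n_bins >= 1)
  n <- nrow(candidates)
  if (n == 0) {
    candidates$bin_id <- integer()
    return(candidates)
  }
  k <- min(n_bins, max(1L, floor(n / min_bin_pairs)))
  d <- candidates$distance
  if (k == 1 || length(unique(d)) == 1) {
    candidates$bin_id <- 1L
    return(candidates)
  }
  # equal-count breaks by order statistic (exact integer arithmetic; a
  # quantile() call here suffers floating-point tie artefacts)
  ord <- sort(d)
  breaks <- unique(ord[(seq_len(k - 1) * n) %/% k])
  bin <- findInterval(d, breaks, left.open = TRUE) + 1L
  bin <- merge_small_bins(bin, min_bin_pairs)
  candidates$bin_id <- bin
  candidates
}

# Relabel bins to consecutive integers and merge any bin smaller than
# min_size into its nearest (by bin order) neighbour, repeatedly.
merge_small_bins <- function(bin, min_size) {
  repeat {
    bin <- match(bin, sort(unique(bin)))
    tab <- tabulate(bin)
    if (length(tab) <= 1 || all(tab >= min_size)) return(bin)
    i <- which.min(tab)
    neighbour <- if (i == 1) 2L else if (i == length(tab)) i - 1L else {
      if (tab[i - 1] <= tab[i + 1]) i - 1L else i + 1L
    }
    bin[bin == i] <- neighbour
  }
}

#' Fit the negative-binomial background model for one distance bin
#'
#' Regresses the combined di-tag count on interactability and distance with
#' a log link and ML-estimated dispersion. For `capture_to_cis` pairs the
#' covariates are the log trans totals of the bait in each replicate plus
#' log distance. For `within_capture` pairs, each replicate contributes a
#' symmetric sum `ln N_T(lo) + ln N_T(hi)` and product
#' `ln N_T(lo) * ln N_T(hi)` term, so the fit is invariant to fragment
#' order, plus log distance. Non-convergence falls back to a Poisson fit
#' (dispersion set to a large sentinel) with a warning; collinear
#' covariates are dropped by the rank-deficient fit and logged.
#'
#' @param candidates Candidates of one class in one bin (needs `y`, `ln_d`
#'   and the `ln_nt_*` columns).
#' @param pair_class `"capture_to_cis"` or `"within_capture"`.
#' @return A `chic_background` object: list with `coefficients`, `size`
#'   (NB dispersion), `n_pairs`, `converged`, `model` (the glm fit), and
#'   `mu_hat` (fitted means, in input row order). An all-zero bin yields a
#'   degenerate fit with `mu_hat ~ 0`.
#' @export
fit_background_model <- function(candidates,
                                 pair_class = c("capture_to_cis",
                                                "within_capture")) {
  pair_class <- match.arg(pair_class)
  reps <- sub("^ln_nt_a_", "",
              grep("^ln_nt_a_", names(candidates), value = TRUE))
  y <- candidates$y
  n <- length(y)
  if (sum(y) == 0) {
    return(structure(
      list(coefficients = c(`(Intercept)` = -Inf), size = Inf,
           n_pairs = n, converged = TRUE, model = NULL,
           mu_hat = rep(1e-12, n), pair_class = pair_class),
      class = "chic_background"
    ))
  }
  X <- data.frame(y = y, ln_d = candidates$ln_d)
  for (r in reps) {
    if (pair_class == "capture_to_cis") {
      X[[paste0("ln_nt_", r)]] <- candidates[[paste0("ln_nt_a_", r)]]
    } else {
      a <- candidates[[paste0("ln_nt_a_", r)]]
      b <- candidates[[paste0("ln_nt_b_", r)]]
      X[[paste0("ln_nt_sum_", r)]] <- a + b
      X[[paste0("ln_nt_prod_", r)]] <- a * b
    }
  }
  form <- stats::as.formula(paste("y ~", paste(setdiff(names(X), "y"),
                                               collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = X,
                                  control = stats::glm.control(maxit = 50))),
    error = function(e) NULL
  )
  size <- if (!is.null(fit)) fit$theta else NA_real_
  converged <- !is.null(fit) && isTRUE(fit$converged) &&
    is.finite(size) && size > 0
  if (!converged) {
    warning("NB background fit did not converge in one bin; ",
            "falling back to Poisson")
    fit <- stats::glm(form, data = X, family = stats::poisson())
    size <- 1e8
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    message("collinear covariate(s) dropped in background fit: ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  structure(
    list(coefficients = cf, size = size, n_pairs = n,
         converged = converged, model = fit,
         mu_hat = as.numeric(stats::fitted(fit)), pair_class = pair_class),
    class = "chic_background"
  )
}

#' @export
print.chic_background <- function(x, ...) {
  cat(sprintf("NB background fit (%s): %d pairs, size = %.3g%s\n",
              x$pair_class, x$n_pairs, x$size,
              if (x$converged) "" else " [Poisson fallback]"))
  print(x$coefficients)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chic_background <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @exportS3Method generics::glance
glance.chic_background <- function(x, ...) {
  tibble::tibble(pair_class = x$pair_class, size = x$size,
                 n_pairs = x$n_pairs, converged = x$converged)
}

#' Upper-tail negative-binomial p-value for an observed pair count
#'
#' `p = P(Y >= y)` under NB(mean `mu_hat`, dispersion `size`); `y = 0`
#' gives `p = 1`. Vectorised.
#'
#' @param y Observed counts (non-negative integers).
#' @param mu_hat Fitted background means (> 0).
#' @param size NB dispersion (> 0).
#' @return P-values in `[0, 1]`.
#' @export
pair_pvalue <- function(y, mu_hat, size) {
  stopifnot(all(y >= 0), all(mu_hat > 0), all(size > 0))
  ifelse(y == 0, 1,
         pnbinom(y - 1, mu = mu_hat, size = size, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment within groups
#'
#' Step-up FDR adjustment applied independently within each group (here:
#' locus x cell line x ligation class).
#'
#' @param p P-values in `[0, 1]`.
#' @param group Grouping vector (same length as `p`); scalars are recycled.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_fdr <- function(p, group = 1L) {
  stopifnot(all(p >= 0 & p <= 1))
  if (length(group) == 1) group <- rep(group, length(p))
  stopifnot(length(group) == length(p))
  out <- numeric(length(p))
  for (g in unique(group)) {
    sel <- which(group == g)
    out[sel] <- stats::p.adjust(p[sel], method = "BH")
  }
  out
}

#' Call significant interaction peaks from a tested pair table
#'
#' A pair is a peak iff its FDR-adjusted p-value is below `alpha` and its
#' midpoint distance lies within `[min_dist, max_dist]`. Output is sorted
#' by locus then adjusted p.
#'
#' @param tested Tibble with at least `locus_id`, `p_adj`, `distance`.
#' @param alpha Significance threshold on adjusted p; default 0.01.
#' @param min_dist,max_dist Distance window; defaults 1e4 / 5e6.
#' @return The input with a logical `significant` column, sorted.
#' @export
call_peaks <- function(tested, alpha = 0.01, min_dist = 1e4,
                       max_dist = 5e6) {
  tested |>
    dplyr::mutate(significant = .data$p_adj < alpha &
                    .data$distance >= min_dist &
                    .data$distance <= max_dist) |>
    dplyr::arrange(.data$locus_id, .data$p_adj)
}

#' Full peak test for one cell line
#'
#' Bins candidates per ligation class, fits per-bin NB background models,
#' computes upper-tail p-values and per-(locus, class) BH-adjusted
#' p-values, and flags significant peaks.
#'
#' @param candidates Output of [enumerate_candidate_pairs()].
#' @param cell_line Cell line label attached to the output.
#' @param alpha FDR threshold; default 0.01.
#' @param n_bins,min_bin_pairs Binning parameters
#'   (see [assign_distance_bins()]).
#' @param min_dist,max_dist Distance window for significance.
#' @return List with `peaks` (tested pair tibble incl. `expected`, `p`,
#'   `p_adj`, `significant`) and `fits` (per class, list of
#'   `chic_background` by bin).
#' @export
test_candidate_pairs <- function(candidates, cell_line = "cell",
                                 alpha = 0.01, n_bins = 100,
                                 min_bin_pairs = 200,
                                 min_dist = 1e4, max_dist = 5e6) {
  fits <- list()
  tested <- candidates |>
    dplyr::group_split(.data$pair_class) |>
    purrr::map(function(cls_df) {
      cls <- cls_df$pair_class[1]
      cls_df <- assign_distance_bins(cls_df, n_bins = n_bins,
                                     min_bin_pairs = min_bin_pairs)
      bin_fits <- list()
      out <- cls_df |>
        dplyr::group_split(.data$bin_id) |>
        purrr::map(function(bdf) {
          fit <- fit_background_model(bdf, pair_class = cls)
          bin_fits[[as.character(bdf$bin_id[1])]] <<- fit
          bdf$expected <- fit$mu_hat
          bdf$p <- pair_pvalue(bdf$y, pmax(fit$mu_hat, 1e-12), fit$size)
          bdf
        }) |>
        dplyr::bind_rows()
      fits[[cls]] <<- bin_fits
      out
    }) |>
    dplyr::bind_rows()
  if (nrow(tested) == 0) {
    return(list(peaks = tested, fits = fits))
  }
  tested$p_adj <- adjust_fdr(tested$p,
                             paste(tested$locus_id, tested$pair_class))
  peaks <- call_peaks(tested, alpha = alpha, min_dist = min_dist,
                      max_dist = max_dist) |>
    dplyr::mutate(cell_line = cell_line, .before = 1) |>
    dplyr::select("cell_line", "frag_lo", "frag_hi", "pair_class",
                  "locus_id", "distance", observed = "y", "expected",
                  "p", "p_adj", "significant")
  list(peaks = peaks, fits = fits)
}
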