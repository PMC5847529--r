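#' Run the full CHi-C peak-calling pipeline
#'
#' Orchestrates, per cell line: interactability filtering (truncated NB
#' fit per replicate, 5% thresholds), candidate enumeration, background
#' model fitting, p-values and per-locus BH FDR, and peak calling; then
#' across cell lines: replicate QC, locus summaries, peak sharing,
#' Jaccard clustering and (when gene models are supplied) target-gene
#' assignment with nearest-gene comparison. Deterministic given inputs and
#' the configuration.
#'
#' @param cell_data Named list (one element per cell line), each a list
#'   with `pair_counts` (long tibble: `frag_lo`, `frag_hi`,
#'   `replicate_id`, `count`, `pair_class`, `distance`) and
#'   `trans_counts` (`frag_id`, `replicate_id`, `n_trans`).
#' @param fragment_map Fragment map with captured flags.
#' @param loci Locus tibble from [define_loci()].
#' @param genes Optional gene tibble (refFlat-like columns; see
#'   [read_genes_tsv()]).
#' @param risk_snps Optional risk-SNP tibble (for nearest-gene calls).
#' @param alpha FDR threshold; default 0.01.
#' @param min_dist,max_dist Distance window in bp; defaults 1e4 / 5e6.
#' @param n_bins,min_bin_pairs Distance-binning parameters.
#' @param truncation `"valley"` or `"manual"`; `manual_t` may be a nested
#'   list `cell_line -> replicate -> t`.
#' @param manual_t Manual truncation points (see [fit_interactability_filters()]).
#' @param verbose Log filtering counts to stderr; default TRUE.
#' @return A `chic_run` list: `peaks` (all tested pairs, all cell lines),
#'   `significant` (peak subset), `filters` (interactability report),
#'   `qc` (replicate correlations), `locus_summary`, `comparison`
#'   (overlap counts + Jaccard, when >= 2 cell lines), `targets`,
#'   `nearest`, `agreement` (when genes given), `universes` (tested pair
#'   keys per cell line).
#' @export
run_chic_pipeline <- function(cell_data, fragment_map, loci, genes = NULL,
                              risk_snps = NULL, alpha = 0.01,
                              min_dist = 1e4, max_dist = 5e6,
                              n_bins = 100, min_bin_pairs = 200,
                              truncation = c("valley", "manual"),
                              manual_t = NULL, verbose = TRUE) {
  truncation <- match.arg(truncation)
  stopifnot(length(cell_data) >= 1, !is.null(names(cell_data)))
  say <- function(...) if (verbose) message(...)
  filters <- list()
  qc <- list()
  results <- purrr::imap(cell_data, function(dat, cl) {
    reps <- sort(unique(dat$trans_counts$replicate_id))
    if (length(reps) < 2) {
      stop("cell line ", cl, " needs at least two replicates")
    }
    fits <- fit_interactability_filters(
      dat$trans_counts, method = truncation,
      manual_t = if (truncation == "manual") manual_t[[cl]] else NULL
    )
    filt <- filter_fragments(dat$trans_counts, fits)
    filters[[cl]] <<- interactability_report(fits, filt, cell_line = cl)
    say(sprintf("[%s] %d/%d captured fragments kept (%.1f%% excluded)",
                cl, sum(filt$kept), nrow(filt),
                100 * mean(!filt$kept)))
    qc[[cl]] <<- dplyr::mutate(spearman_by_stratum(dat$pair_counts),
                               cell_line = cl, .before = 1)
    cand <- enumerate_candidate_pairs(
      fragment_map, filt$frag_id[filt$kept], dat$pair_counts,
      dat$trans_counts, loci, min_dist = min_dist, max_dist = max_dist
    )
    say(sprintf("[%s] %d candidate pairs (%d within-capture)", cl,
                nrow(cand), sum(cand$pair_class == "within_capture")))
    res <- test_candidate_pairs(cand, cell_line = cl, alpha = alpha,
                                n_bins = n_bins,
                                min_bin_pairs = min_bin_pairs,
                                min_dist = min_dist, max_dist = max_dist)
    say(sprintf("[%s] %d significant peaks", cl,
                sum(res$peaks$significant)))
    res
  })
  peaks <- dplyr::bind_rows(purrr::map(results, "peaks"))
  significant <- dplyr::filter(peaks, .data$significant)
  universes <- purrr::map(results, function(r) {
    pair_key(r$peaks$frag_lo, r$peaks$frag_hi)
  })
  peaksets <- purrr::map(results, function(r) {
    sig <- dplyr::filter(r$peaks, .data$significant)
    pair_key(sig$frag_lo, sig$frag_hi)
  })
  comparison <- NULL
  if (length(cell_data) >= 2) {
    comparison <- list(
      overlap = peak_overlap_sets(peaksets),
      jaccard = jaccard_dendrogram(peaksets)
    )
  }
  targets <- nearest <- agreement <- NULL
  if (!is.null(genes)) {
    genes_mapped <- map_tss_to_fragments(genes, fragment_map)
    direct <- assign_target_genes(peaks, loci, genes_mapped,
                                  fragment_map, max_dist = max_dist)
    adjacent <- assign_adjacent_locus_targets(peaks, loci, direct,
                                              fragment_map,
                                              max_dist = max_dist)
    targets <- dplyr::bind_rows(direct, adjacent)
    if (!is.null(risk_snps)) {
      nearest <- nearest_gene(risk_snps, genes_mapped)
      agreement <- compare_chic_vs_nearest(targets, nearest, loci)
    }
  }
  structure(
    list(peaks = peaks, significant = significant,
         filters = dplyr::bind_rows(filters),
         qc = dplyr::bind_rows(qc),
         locus_summary = summarize_loci(peaks, loci),
         comparison = comparison, targets = targets, nearest = nearest,
         agreement = agreement, universes = universes,
         peaksets = peaksets,
         params = list(alpha = alpha, min_dist = min_dist,
                       max_dist = max_dist, n_bins = n_bins,
                       min_bin_pairs = min_bin_pairs)),
    class = "chic_run"
  )
}

#' @export
print.chic_run <- function(x, ...) {
  cat("CHi-C pipeline run\n")
  cat(sprintf("  cell lines: %s\n",
              paste(names(x$universes), collapse = ", ")))
  cat(sprintf("  tested pairs: %d; significant peaks: %d (alpha = %g)\n",
              nrow(x$peaks), nrow(x$significant), x$params$alpha))
  if (!is.null(x$targets)) {
    cat(sprintf("  target genes: %d at %d loci\n",
                dplyr::n_distinct(x$targets$gene),
                dplyr::n_distinct(x$targets$locus_id)))
  }
  invisible(x)
}

#' Per-locus peak summary across cell lines
#'
#' Peak count, median peak distance and count of long-range (> 2 Mb)
#' peaks per risk locus and cell line; a locus is informative when it has
#' at least one significant peak in at least one cell line.
#'
#' @param peaks Tested-pair tibble with `significant` flags (all cell
#'   lines).
#' @param loci Locus tibble.
#' @param long_range Distance above which a peak counts as long-range;
#'   default 2e6.
#' @return Tibble `locus_id`, `cell_line`, `n_peaks`, `median_distance`,
#'   `n_long_range`, `informative` (locus-level flag, repeated).
#' @export
summarize_loci <- function(peaks, loci, long_range = 2e6) {
  risk <- dplyr::filter(loci, .data$is_risk)
  cells <- unique(peaks$cell_line)
  if (length(cells) == 0) cells <- character()
  grid <- tidyr::expand_grid(locus_id = risk$locus_id, cell_line = cells)
  sig <- dplyr::filter(peaks, .data$significant)
  per <- sig |>
    dplyr::group_by(.data$locus_id, .data$cell_line) |>
    dplyr::summarise(n_peaks = dplyr::n(),
                     median_distance = median(.data$distance),
                     n_long_range = sum(.data$distance > long_range),
                     .groups = "drop")
  out <- grid |>
    dplyr::left_join(per, by = c("locus_id", "cell_line")) |>
    dplyr::mutate(
      n_peaks = dplyr::coalesce(.data$n_peaks, 0L),
      n_long_range = dplyr::coalesce(.data$n_long_range, 0L)
    )
  informative <- out |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(informative = any(.data$n_peaks > 0))
  dplyr::left_join(out, informative, by = "locus_id") |>
    dplyr::arrange(.data$locus_id, .data$cell_line)
}
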