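#' Distance-stratified Spearman correlation between replicates
#'
#' Reproducibility check between the two biological replicates of one cell
#' line: for each ligation class and distance stratum, the Spearman rank
#' correlation (average ranks for ties) of pair counts across all fragment
#' pairs observed in at least one replicate. Pairs with zero counts in both
#' replicates are excluded. Default strata: 0-500 kb, 500 kb-1 Mb,
#' 1-1.5 Mb, > 1.5 Mb (half-open `[lo, hi)`).
#'
#' @param pair_counts Long pair-count tibble (`frag_lo`, `frag_hi`,
#'   `replicate_id`, `count`, `pair_class`, `distance`) with exactly two
#'   replicate ids.
#' @param strata Numeric vector of stratum boundaries in bp.
#' @return Tibble `pair_class`, `stratum`, `rho`, `n_pairs`; `rho` is `NA`
#'   when fewer than two usable pairs fall in a stratum.
#' @export
spearman_by_stratum <- function(pair_counts,
                                strata = c(0, 5e5, 1e6, 1.5e6, Inf)) {
  reps <- sort(unique(pair_counts$replicate_id))
  stopifnot(length(reps) == 2)
  labels <- stratum_labels(strata)
  wide <- pair_counts |>
    tidyr::pivot_wider(
      id_cols = c("frag_lo", "frag_hi", "pair_class", "distance"),
      names_from = "replicate_id", values_from = "count", values_fill = 0L
    ) |>
    dplyr::filter(.data[[reps[1]]] > 0 | .data[[reps[2]]] > 0) |>
    dplyr::mutate(stratum = labels[findInterval(.data$distance, strata)])
  grid <- tidyr::expand_grid(
    pair_class = sort(unique(pair_counts$pair_class)),
    stratum = labels
  )
  got <- wide |>
    dplyr::group_by(.data$pair_class, .data$stratum) |>
    dplyr::summarise(
      rho = if (dplyr::n() >= 2) {
        suppressWarnings(stats::cor(.data[[reps[1]]], .data[[reps[2]]],
                                    method = "spearman"))
      } else NA_real_,
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
  grid |>
    dplyr::left_join(got, by = c("pair_class", "stratum")) |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L),
                  stratum = factor(.data$stratum, levels = labels)) |>
    dplyr::arrange(.data$pair_class, .data$stratum)
}

stratum_labels <- function(strata) {
  fmt <- function(x) {
    ifelse(is.infinite(x), "Inf",
           ifelse(x >= 1e6, paste0(x / 1e6, "Mb"), paste0(x / 1e3, "kb")))
  }
  n <- length(strata)
  lab <- paste0(fmt(strata[-n]), "-", fmt(strata[-1]))
  lab[n - 1] <- paste0(">", fmt(strata[n - 1]))
  lab
}
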