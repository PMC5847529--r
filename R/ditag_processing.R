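#' Classify valid di-tags into analysis classes
#'
#' Each di-tag (one sequenced ligation product, two mapped ends) falls into
#' exactly one class:
#'
#' * `within_capture` — both ends in captured fragments, same chromosome,
#'   midpoint distance of the two fragments at most `max_dist` (ends in two
#'   different capture regions within `max_dist` count here too);
#' * `capture_to_cis` — exactly one end captured, partner on the same
#'   chromosome within `max_dist`;
#' * `trans` — at least one end captured, partner on another chromosome
#'   (retained only for the trans-ligation totals `N_T`);
#' * `out_of_range` — captured end with a same-chromosome partner beyond
#'   `max_dist` (discarded from peak calling);
#' * `off_target` — neither end captured (discarded);
#' * `same_fragment` — both ends in one fragment (invalid upstream; dropped
#'   with a warning if present).
#'
#' @param ditags Tibble with columns `replicate_id`, `chromA`, `posA`,
#'   `chromB`, `posB` (positions 1-based).
#' @param fragment_map Fragment map with `captured` flags set
#'   (see [mark_captured()]).
#' @param max_dist Maximum cis midpoint distance in bp; default 5e6.
#' @return The input tibble with columns `frag_a`, `frag_b` (fragment ids of
#'   the two ends), `distance` (midpoint distance, `NA` for trans) and
#'   `class` appended.
#' @export
classify_ditags <- function(ditags, fragment_map, max_dist = 5e6) {
  ditags <- tibble::as_tibble(ditags)
  stopifnot(all(c("replicate_id", "chromA", "posA", "chromB", "posB") %in%
                  names(ditags)))
  frag_a <- locate_fragment(fragment_map, ditags$chromA, ditags$posA)
  frag_b <- locate_fragment(fragment_map, ditags$chromB, ditags$posB)
  cap <- fragment_map$captured
  cap_a <- cap[match(frag_a, fragment_map$frag_id)]
  cap_b <- cap[match(frag_b, fragment_map$frag_id)]
  dist <- fragment_distance(fragment_map, frag_a, frag_b)
  cis <- !is.na(dist)
  cls <- dplyr::case_when(
    frag_a == frag_b ~ "same_fragment",
    !cap_a & !cap_b ~ "off_target",
    !cis ~ "trans",
    cap_a & cap_b & dist <= max_dist ~ "within_capture",
    xor(cap_a, cap_b) & dist <= max_dist ~ "capture_to_cis",
    .default = "out_of_range"
  )
  if (any(cls == "same_fragment")) {
    warning(sum(cls == "same_fragment"),
            " di-tag(s) with both ends in one fragment; dropped downstream")
  }
  dplyr::mutate(ditags, frag_a = frag_a, frag_b = frag_b,
                distance = dist, class = cls)
}

# Fragment containing a 1-based position (0-based half-open intervals).
# Errors if the position lies beyond the chromosome extent.
locate_fragment <- function(fragment_map, chrom, pos) {
  stopifnot(all(pos >= 1))
  pos0 <- pos - 1
  out <- rep(NA_integer_, length(chrom))
  for (ch in unique(chrom)) {
    fm <- fragment_map[fragment_map$chrom == ch, ]
    if (nrow(fm) == 0) stop("unknown chromosome: ", ch)
    sel <- which(chrom == ch)
    p <- pos0[sel]
    if (any(p >= max(fm$end))) {
      stop("position beyond extent of chromosome ", ch)
    }
    out[sel] <- fm$frag_id[findInterval(p, fm$start)]
  }
  out
}

#' Aggregate classified di-tags into fragment-pair counts
#'
#' Collapses di-tags to one row per canonical unordered fragment pair
#' (`frag_lo < frag_hi`) and replicate, keeping only the two cis analysis
#' classes. The result is invariant to di-tag order and to swapping ends.
#'
#' @param classified Output of [classify_ditags()].
#' @param fragment_map Fragment map (for distances).
#' @param replicate_ids Optional character vector of expected replicate ids;
#'   an unknown replicate id in the data is an error.
#' @return Pair-count tibble: `frag_lo`, `frag_hi`, `replicate_id`, `count`,
#'   `pair_class`, `distance`.
#' @export
aggregate_pair_counts <- function(classified, fragment_map,
                                  replicate_ids = NULL) {
  if (!is.null(replicate_ids)) {
    bad <- setdiff(unique(classified$replicate_id), replicate_ids)
    if (length(bad) > 0) {
      stop("unknown replicate id: ", paste(bad, collapse = ", "))
    }
  }
  kept <- dplyr::filter(classified,
                        .data$class %in% c("within_capture", "capture_to_cis"))
  if (nrow(kept) == 0) {
    return(tibble::tibble(frag_lo = integer(), frag_hi = integer(),
                          replicate_id = character(), count = integer(),
                          pair_class = character(), distance = double()))
  }
  kept |>
    dplyr::mutate(frag_lo = pmin(.data$frag_a, .data$frag_b),
                  frag_hi = pmax(.data$frag_a, .data$frag_b)) |>
    dplyr::count(.data$frag_lo, .data$frag_hi, .data$replicate_id,
                 .data$class, name = "count") |>
    dplyr::rename(pair_class = "class") |>
    dplyr::mutate(distance = fragment_distance(fragment_map,
                                               .data$frag_lo,
                                               .data$frag_hi)) |>
    dplyr::arrange(.data$frag_lo, .data$frag_hi, .data$replicate_id)
}

#' Per-fragment trans-ligation totals (interactability N_T)
#'
#' For every captured fragment and replicate, counts di-tags with one end in
#' that fragment and the partner on a different chromosome. Trans ligations
#' are assumed to be predominantly random, so this total measures the
#' fragment's generic propensity to form ligations. Captured fragments with
#' no trans di-tags get `n_trans = 0`.
#'
#' @param classified Output of [classify_ditags()].
#' @param fragment_map Fragment map with `captured` flags.
#' @param replicate_ids Optional character vector of replicates to report
#'   (defaults to those present in the data).
#' @return Tibble `frag_id`, `replicate_id`, `n_trans` for every captured
#'   fragment x replicate.
#' @export
compute_trans_counts <- function(classified, fragment_map,
                                 replicate_ids = NULL) {
  if (is.null(replicate_ids)) {
    replicate_ids <- sort(unique(classified$replicate_id))
  }
  trans <- dplyr::filter(classified, .data$class == "trans")
  captured_ids <- fragment_map$frag_id[fragment_map$captured]
  ends <- dplyr::bind_rows(
    dplyr::select(trans, frag_id = "frag_a", "replicate_id"),
    dplyr::select(trans, frag_id = "frag_b", "replicate_id")
  ) |>
    dplyr::filter(.data$frag_id %in% captured_ids) |>
    dplyr::count(.data$frag_id, .data$replicate_id, name = "n_trans")
  grid <- tidyr::expand_grid(frag_id = captured_ids,
                             replicate_id = replicate_ids)
  grid |>
    dplyr::left_join(ends, by = c("frag_id", "replicate_id")) |>
    dplyr::mutate(n_trans = dplyr::coalesce(.data$n_trans, 0L)) |>
    dplyr::arrange(.data$frag_id, .data$replicate_id)
}
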