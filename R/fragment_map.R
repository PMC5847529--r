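#' In silico restriction digestion of a nucleotide sequence
#'
#' Cuts a sequence at every exact occurrence of a restriction recognition
#' site, placing each boundary `cut_offset` bases into the site (HindIII,
#' `A^AGCTT`, cuts one base in). Coordinates are 0-based, half-open, the
#' convention used for all intervals in this package.
#'
#' @param sequence Character scalar over the alphabet `A`, `C`, `G`, `T`, `N`.
#' @param recognition_site Recognition sequence; default `"AAGCTT"` (HindIII).
#' @param cut_offset Offset of the cut within the site, between 0 and
#'   `nchar(recognition_site)`. Default 1 (`A^AGCTT`).
#' @return A tibble with columns `start`, `end` (0-based half-open) tiling
#'   `[0, nchar(sequence))`. A sequence with no site yields one fragment.
#' @examples
#' digest_sequence("ACGTAAAGCTTACGTACGTA")
#' @export
digest_sequence <- function(sequence, recognition_site = "AAGCTT",
                            cut_offset = 1) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) {
    stop("`sequence` must be non-empty")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("`sequence` may only contain A, C, G, T, N")
  }
  if (cut_offset < 0 || cut_offset > nchar(recognition_site)) {
    stop("`cut_offset` must lie within the recognition site")
  }
  hits <- gregexpr(recognition_site, sequence, fixed = TRUE)[[1]]
  len <- nchar(sequence)
  if (hits[1] == -1) {
    return(tibble::tibble(start = 0, end = len))
  }
  cuts <- as.integer(hits) - 1L + as.integer(cut_offset)
  cuts <- cuts[cuts > 0 & cuts < len]
  bounds <- c(0L, sort(unique(cuts)), len)
  tibble::tibble(start = bounds[-length(bounds)], end = bounds[-1])
}

#' Build a fragment map for one or more digested chromosomes
#'
#' Assembles per-chromosome fragment tables into a genome-wide fragment map
#' with strictly increasing fragment ids in genome order.
#'
#' @param fragments_by_chrom Named list of tibbles with `start`/`end`
#'   columns (one element per chromosome), or a single tibble with a
#'   `chrom` column.
#' @return A fragment map tibble: `chrom`, `start`, `end`, `frag_id`,
#'   `captured` (all `FALSE` until [mark_captured()]), `region_id` (`NA`).
#' @export
new_fragment_map <- function(fragments_by_chrom) {
  if (is.data.frame(fragments_by_chrom)) {
    stopifnot("chrom" %in% names(fragments_by_chrom))
    frags <- tibble::as_tibble(fragments_by_chrom)
  } else {
    frags <- purrr::imap(fragments_by_chrom, function(df, nm) {
      dplyr::mutate(tibble::as_tibble(df), chrom = nm, .before = 1)
    })
    frags <- dplyr::bind_rows(frags)
  }
  stopifnot(all(frags$start < frags$end))
  frags <- dplyr::arrange(frags, .data$chrom, .data$start)
  ok <- frags |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      tiled = all(.data$start[-1] == .data$end[-dplyr::n()]) || dplyr::n() == 1
    )
  if (!all(ok$tiled)) {
    stop("fragments must tile each chromosome without gaps or overlaps")
  }
  frags |>
    dplyr::ungroup() |>
    dplyr::mutate(
      frag_id = dplyr::row_number(),
      captured = FALSE,
      region_id = NA_character_
    ) |>
    dplyr::select("chrom", "start", "end", "frag_id", "captured", "region_id")
}

#' Flag fragments overlapping capture regions
#'
#' A fragment is captured iff it overlaps at least one capture region by at
#' least 1 bp (intervals half-open). A fragment spanning two regions is
#' assigned the first overlapping region in coordinate order.
#'
#' @param fragment_map Fragment map tibble (see [new_fragment_map()]).
#' @param capture_regions Tibble with `chrom`, `start`, `end`, `region_id`.
#' @return The fragment map with updated `captured` and `region_id`.
#' @export
mark_captured <- function(fragment_map, capture_regions) {
  capture_regions <- tibble::as_tibble(capture_regions)
  stopifnot(all(c("chrom", "start", "end", "region_id") %in%
                  names(capture_regions)))
  unknown <- setdiff(capture_regions$chrom, fragment_map$chrom)
  if (length(unknown) > 0) {
    stop("capture region on unknown chromosome: ",
         paste(unknown, collapse = ", "))
  }
  regions <- dplyr::arrange(capture_regions, .data$chrom, .data$start)
  hits <- dplyr::inner_join(
    dplyr::select(fragment_map, "chrom", "start", "end", "frag_id"),
    dplyr::select(regions, "chrom",
                  r_start = "start", r_end = "end", "region_id"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$start < .data$r_end, .data$r_start < .data$end) |>
    dplyr::arrange(.data$frag_id, .data$r_start) |>
    dplyr::distinct(.data$frag_id, .keep_all = TRUE) |>
    dplyr::select("frag_id", "region_id")
  fragment_map |>
    dplyr::select(-"captured", -"region_id") |>
    dplyr::left_join(hits, by = "frag_id") |>
    dplyr::mutate(captured = !is.na(.data$region_id)) |>
    dplyr::select("chrom", "start", "end", "frag_id", "captured", "region_id")
}

#' Merge capture regions into analysis loci
#'
#' A locus is a run of capture regions on one chromosome whose pairwise gaps
#' are at most `merge_gap`, annotated by at least one risk SNP. Regions
#' carrying no risk SNP are flagged non-risk and excluded from locus-level
#' reporting.
#'
#' @param capture_regions Tibble `chrom`, `start`, `end`, `region_id`.
#' @param risk_snps Tibble `rsid`, `chrom`, `pos` (1-based).
#' @param merge_gap Maximum gap (bp) between regions merged into one locus.
#'   Default 0: merge only overlapping or book-ended regions.
#' @return Tibble of loci: `locus_id`, `chrom`, `start`, `end` (hull),
#'   `member_region_ids` (list), `snp_ids` (list), `n_snps`, `is_risk`.
#' @export
define_loci <- function(capture_regions, risk_snps, merge_gap = 0) {
  stopifnot(merge_gap >= 0)
  regions <- dplyr::arrange(tibble::as_tibble(capture_regions),
                            .data$chrom, .data$start)
  snps <- tibble::as_tibble(risk_snps)
  stopifnot(all(snps$pos >= 1))
  # SNP positions are 1-based; interval arithmetic is 0-based half-open
  region_snps <- dplyr::inner_join(
    regions,
    dplyr::transmute(snps, chrom = .data$chrom, pos0 = .data$pos - 1,
                     rsid = .data$rsid),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$pos0 >= .data$start, .data$pos0 < .data$end) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(snp_ids = list(sort(.data$rsid)))
  regions <- dplyr::left_join(regions, region_snps, by = "region_id")
  regions$snp_ids <- purrr::map(regions$snp_ids,
                                \(x) if (is.null(x)) character() else x)
  regions <- regions |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      gap = .data$start - dplyr::lag(cummax(as.numeric(.data$end)),
                                     default = -Inf),
      new_run = as.integer(.data$gap > .env$merge_gap),
      run = cumsum(ifelse(is.na(.data$new_run), 1L, .data$new_run))
    ) |>
    dplyr::ungroup()
  loci <- regions |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      member_region_ids = list(.data$region_id),
      snp_ids = list(sort(unique(unlist(.data$snp_ids)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(
      locus_id = paste0("locus_", dplyr::row_number()),
      n_snps = lengths(.data$snp_ids),
      is_risk = .data$n_snps > 0
    ) |>
    dplyr::select("locus_id", "chrom", "start", "end",
                  "member_region_ids", "snp_ids", "n_snps", "is_risk")
  loci
}

#' Midpoint distance between two fragments
#'
#' Distance between fragment midpoints, `floor((start + end) / 2)` each,
#' in bp. Vectorised. Pairs on different chromosomes (trans) yield `NA`.
#'
#' @param chromA,startA,endA,chromB,startB,endB Fragment coordinates
#'   (0-based half-open).
#' @return Numeric vector of distances in bp; `NA` for trans pairs.
#' @export
midpoint_distance <- function(chromA, startA, endA, chromB, startB, endB) {
  midA <- floor((startA + endA) / 2)
  midB <- floor((startB + endB) / 2)
  ifelse(chromA == chromB, abs(midA - midB), NA_real_)
}

#' Midpoint distance between fragment ids in a fragment map
#'
#' @param fragment_map Fragment map tibble.
#' @param frag_a,frag_b Vectors of fragment ids.
#' @return Numeric distances in bp (`NA` for trans pairs).
#' @export
fragment_distance <- function(fragment_map, frag_a, frag_b) {
  idx <- match(frag_a, fragment_map$frag_id)
  jdx <- match(frag_b, fragment_map$frag_id)
  midpoint_distance(
    fragment_map$chrom[idx], fragment_map$start[idx], fragment_map$end[idx],
    fragment_map$chrom[jdx], fragment_map$start[jdx], fragment_map$end[jdx]
  )
}

#' Map region ids to locus ids
#'
#' @param loci Locus tibble from [define_loci()].
#' @return Tibble `region_id`, `locus_id`, `is_risk`.
#' @export
region_locus_map <- function(loci) {
  tidyr::unnest(
    dplyr::select(loci, "locus_id", "is_risk",
                  region_id = "member_region_ids"),
    "region_id"
  )
}
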