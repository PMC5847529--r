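#' Read and write the package's plain-text interchange formats
#'
#' Fragment maps and capture regions travel as BED4 (chrom, start, end,
#' name; 0-based half-open, no header); risk SNPs, di-tags, pre-aggregated
#' pair counts and gene models as headered TSV; peaks as BEDPE or WashU
#' longrange text.
#'
#' @param path File path.
#' @return A tibble (readers) or the input, invisibly (writers).
#' @name chic_io
NULL

#' @rdname chic_io
#' @param fragment_map Fragment map tibble.
#' @export
write_fragment_bed <- function(fragment_map, path) {
  readr::write_tsv(
    dplyr::select(fragment_map, "chrom", "start", "end", "frag_id"),
    path, col_names = FALSE
  )
  invisible(fragment_map)
}

#' @rdname chic_io
#' @export
read_fragment_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "frag_id"),
                         col_types = "ciii", progress = FALSE)
  new_fragment_map(bed)
}

#' @rdname chic_io
#' @param capture_regions Capture-region tibble.
#' @export
write_capture_bed <- function(capture_regions, path) {
  readr::write_tsv(
    dplyr::select(capture_regions, "chrom", "start", "end", "region_id"),
    path, col_names = FALSE
  )
  invisible(capture_regions)
}

#' @rdname chic_io
#' @export
read_capture_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                      "region_id"),
                  col_types = "ciic", progress = FALSE)
}

#' @rdname chic_io
#' @export
read_snps_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' @rdname chic_io
#' @export
read_ditags_tsv <- function(path) {
  readr::read_tsv(path,
                  col_types = readr::cols(
                    replicate_id = readr::col_character(),
                    chromA = readr::col_character(),
                    posA = readr::col_double(),
                    chromB = readr::col_character(),
                    posB = readr::col_double()
                  ), progress = FALSE)
}

#' @rdname chic_io
#' @param pair_counts Long pair-count tibble.
#' @export
write_pair_counts_tsv <- function(pair_counts, path) {
  readr::write_tsv(pair_counts, path)
  invisible(pair_counts)
}

#' @rdname chic_io
#' @export
read_pair_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    replicate_id = readr::col_character()
  ), progress = FALSE)
}

#' @rdname chic_io
#' @export
read_genes_tsv <- function(path) {
  readr::read_tsv(path,
                  col_types = readr::cols(
                    name = readr::col_character(),
                    chrom = readr::col_character(),
                    strand = readr::col_character(),
                    txStart = readr::col_double(),
                    txEnd = readr::col_double(),
                    biotype = readr::col_character()
                  ), progress = FALSE)
}

# -log2(p_adj), capped so p_adj = 0 serialises to a finite score
peak_score <- function(p_adj, cap = 1000) {
  pmin(-log2(pmax(p_adj, 2^-cap)), cap)
}

#' @rdname chic_io
#' @param peaks Significant-peak tibble (see [test_candidate_pairs()]).
#' @param fragment_map Fragment map giving end coordinates.
#' @export
write_peaks_bedpe <- function(peaks, fragment_map, path) {
  fm <- fragment_map
  i <- match(peaks$frag_lo, fm$frag_id)
  j <- match(peaks$frag_hi, fm$frag_id)
  bedpe <- tibble::tibble(
    chrom1 = fm$chrom[i], start1 = fm$start[i], end1 = fm$end[i],
    chrom2 = fm$chrom[j], start2 = fm$start[j], end2 = fm$end[j],
    name = pair_key(peaks$frag_lo, peaks$frag_hi),
    score = round(peak_score(peaks$p_adj)),
    strand1 = ".", strand2 = ".",
    observed = peaks$observed, expected = peaks$expected,
    p = peaks$p, p_adj = peaks$p_adj,
    pair_class = peaks$pair_class, cell_line = peaks$cell_line
  )
  readr::write_tsv(bedpe, path, col_names = FALSE)
  invisible(peaks)
}

#' @rdname chic_io
#' @export
read_peaks_bedpe <- function(path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2", "observed",
            "expected", "p", "p_adj", "pair_class", "cell_line")
  bedpe <- readr::read_tsv(path, col_names = cols,
                           col_types = "ciiciiciccidddcc",
                           progress = FALSE)
  ids <- strsplit(bedpe$name, ":", fixed = TRUE)
  bedpe |>
    dplyr::mutate(
      frag_lo = as.integer(purrr::map_chr(ids, 1)),
      frag_hi = as.integer(purrr::map_chr(ids, 2))
    )
}

#' @rdname chic_io
#' @export
write_longrange <- function(peaks, fragment_map, path) {
  fm <- fragment_map
  i <- match(peaks$frag_lo, fm$frag_id)
  j <- match(peaks$frag_hi, fm$frag_id)
  score <- peak_score(peaks$p_adj)
  fmt <- function(ci, si, ei, cj, sj, ej) {
    sprintf("%s\t%d\t%d\t%s:%d-%d,%.4f", ci, si, ei, cj, sj, ej, score)
  }
  lines <- c(
    fmt(fm$chrom[i], fm$start[i], fm$end[i],
        fm$chrom[j], fm$start[j], fm$end[j]),
    fmt(fm$chrom[j], fm$start[j], fm$end[j],
        fm$chrom[i], fm$start[i], fm$end[i])
  )
  writeLines(lines, path)
  invisible(peaks)
}

#' @rdname chic_io
#' @export
read_longrange <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  anchor2 <- purrr::map_chr(parts, 4)
  m <- regmatches(anchor2,
                  regexec("^([^:]+):([0-9]+)-([0-9]+),(.+)$", anchor2))
  tibble::tibble(
    chrom1 = purrr::map_chr(parts, 1),
    start1 = as.integer(purrr::map_chr(parts, 2)),
    end1 = as.integer(purrr::map_chr(parts, 3)),
    chrom2 = purrr::map_chr(m, 2),
    start2 = as.integer(purrr::map_chr(m, 3)),
    end2 = as.integer(purrr::map_chr(m, 4)),
    score = as.numeric(purrr::map_chr(m, 5))
  )
}
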