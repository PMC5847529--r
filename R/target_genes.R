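#' Map gene transcription start sites to restriction fragments
#'
#' The TSS is `txStart` for `+`-strand genes and `txEnd` for `-`-strand
#' genes (1-based input coordinates). Each TSS is mapped to the fragment
#' containing it. Several genes may share one fragment — the method cannot
#' resolve TSSs a few hundred bp apart. Genes whose TSS falls outside the
#' fragment map are skipped with a warning.
#'
#' @param genes Gene-model tibble: `name`, `chrom`, `strand` (`+`/`-`),
#'   `txStart`, `txEnd` (1-based inclusive), `biotype`
#'   (`coding`/`noncoding`).
#' @param fragment_map Fragment map tibble.
#' @return The gene tibble with `tss` (1-based) and `tss_frag` columns.
#' @export
map_tss_to_fragments <- function(genes, fragment_map) {
  genes <- tibble::as_tibble(genes)
  stopifnot(all(genes$strand %in% c("+", "-")))
  genes$tss <- ifelse(genes$strand == "+", genes$txStart, genes$txEnd)
  genes$tss_frag <- NA_integer_
  for (ch in unique(genes$chrom)) {
    fm <- fragment_map[fragment_map$chrom == ch, ]
    sel <- which(genes$chrom == ch)
    if (nrow(fm) == 0) next
    pos0 <- genes$tss[sel] - 1
    inside <- pos0 >= min(fm$start) & pos0 < max(fm$end)
    genes$tss_frag[sel[inside]] <-
      fm$frag_id[findInterval(pos0[inside], fm$start)]
  }
  dropped <- is.na(genes$tss_frag)
  if (any(dropped)) {
    warning(sum(dropped), " gene(s) with TSS outside the fragment map ",
            "skipped: ", paste(utils::head(genes$name[dropped], 5),
                               collapse = ", "))
    genes <- genes[!dropped, ]
  }
  genes
}

#' Assign direct putative target genes to risk loci
#'
#' A gene is a direct target of a locus when (a) its TSS lies within the
#' locus hull or within `max_dist` of it in cis, and (b) the TSS fragment
#' is an end of at least one significant interaction peak anchored in the
#' locus, in at least two cell lines. "Anchored in the locus" means the
#' peak's assigned `locus_id`; the supporting cell lines need not share the
#' same partner fragment.
#'
#' @param peaks Combined significant-peak tibble across cell lines
#'   (columns `cell_line`, `frag_lo`, `frag_hi`, `significant`).
#' @param loci Locus tibble ([define_loci()]); only risk loci are assigned.
#' @param genes Gene tibble with `tss_frag` ([map_tss_to_fragments()]).
#' @param fragment_map Fragment map (locates peak ends in loci).
#' @param min_cell_lines Support threshold; default 2.
#' @param max_dist Maximum TSS-to-locus distance in bp; default 5e6.
#' @return Tibble `locus_id`, `gene`, `tss_frag`, `mode` (`"direct"`),
#'   `mediator_locus` (`NA`), `supporting_cell_lines` (list),
#'   `n_cell_lines`.
#' @export
assign_target_genes <- function(peaks, loci, genes, fragment_map,
                                min_cell_lines = 2, max_dist = 5e6) {
  sig <- dplyr::filter(peaks, .data$significant)
  risk <- dplyr::filter(loci, .data$is_risk)
  empty <- tibble::tibble(locus_id = character(), gene = character(),
                          tss_frag = integer(), mode = character(),
                          mediator_locus = character(),
                          supporting_cell_lines = list(),
                          n_cell_lines = integer())
  if (nrow(sig) == 0 || nrow(genes) == 0) return(empty)
  # a peak is anchored in every locus containing either of its ends
  rl <- region_locus_map(loci)
  frag_locus <- setNames(
    rl$locus_id[match(fragment_map$region_id, rl$region_id)],
    fragment_map$frag_id
  )
  sig$locus_lo <- unname(frag_locus[as.character(sig$frag_lo)])
  sig$locus_hi <- unname(frag_locus[as.character(sig$frag_hi)])
  anchors <- dplyr::bind_rows(
    dplyr::select(sig, "cell_line", "frag_lo", "frag_hi",
                  locus_id = "locus_lo"),
    dplyr::select(sig, "cell_line", "frag_lo", "frag_hi",
                  locus_id = "locus_hi")
  ) |>
    dplyr::filter(!is.na(.data$locus_id)) |>
    dplyr::distinct()
  ends <- dplyr::bind_rows(
    dplyr::select(anchors, "cell_line", "locus_id", frag = "frag_lo"),
    dplyr::select(anchors, "cell_line", "locus_id", frag = "frag_hi")
  ) |> dplyr::distinct()
  hits <- dplyr::inner_join(
    ends,
    dplyr::select(genes, gene = "name", "chrom", "tss", "tss_frag"),
    by = c(frag = "tss_frag"), relationship = "many-to-many"
  )
  if (nrow(hits) == 0) return(empty)
  hits <- dplyr::inner_join(
    hits,
    dplyr::select(risk, "locus_id", locus_chrom = "chrom",
                  locus_start = "start", locus_end = "end"),
    by = "locus_id"
  ) |>
    dplyr::filter(
      .data$chrom == .data$locus_chrom,
      .data$tss - 1 >= .data$locus_start - .env$max_dist,
      .data$tss - 1 < .data$locus_end + .env$max_dist
    )
  hits |>
    dplyr::group_by(.data$locus_id, .data$gene, tss_frag = .data$frag) |>
    dplyr::summarise(
      supporting_cell_lines = list(sort(unique(.data$cell_line))),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_cell_lines = lengths(.data$supporting_cell_lines),
                  mode = "direct", mediator_locus = NA_character_) |>
    dplyr::filter(.data$n_cell_lines >= min_cell_lines) |>
    dplyr::select("locus_id", "gene", "tss_frag", "mode",
                  "mediator_locus", "supporting_cell_lines",
                  "n_cell_lines") |>
    dplyr::arrange(.data$locus_id, .data$gene)
}

#' Assign target genes via interaction peaks with an adjacent locus
#'
#' A locus gains the direct targets of an adjacent locus (hulls at most
#' `max_dist` apart on one chromosome) when at least one significant
#' inter-locus peak connects the two loci in at least one cell line. The
#' gene's own multi-cell-line support comes from the mediating locus.
#'
#' @param peaks Combined peak tibble (as in [assign_target_genes()]).
#' @param loci Locus tibble.
#' @param direct Direct assignments from [assign_target_genes()].
#' @param fragment_map Fragment map (to locate peak ends in loci).
#' @param max_dist Adjacency threshold in bp; default 5e6.
#' @return Tibble in the same shape as `direct` with `mode = "adjacent"`
#'   and `mediator_locus` set.
#' @export
assign_adjacent_locus_targets <- function(peaks, loci, direct,
                                          fragment_map, max_dist = 5e6) {
  empty <- direct[0, ]
  sig <- dplyr::filter(peaks, .data$significant,
                       .data$pair_class == "within_capture")
  if (nrow(sig) == 0 || nrow(direct) == 0) return(empty)
  rl <- region_locus_map(loci)
  frag_locus <- setNames(
    rl$locus_id[match(fragment_map$region_id, rl$region_id)],
    fragment_map$frag_id
  )
  sig$locus_lo <- unname(frag_locus[as.character(sig$frag_lo)])
  sig$locus_hi <- unname(frag_locus[as.character(sig$frag_hi)])
  inter <- sig |>
    dplyr::filter(!is.na(.data$locus_lo), !is.na(.data$locus_hi),
                  .data$locus_lo != .data$locus_hi) |>
    dplyr::distinct(.data$locus_lo, .data$locus_hi)
  if (nrow(inter) == 0) return(empty)
  # both directions: X gains from Y and Y gains from X
  links <- dplyr::bind_rows(
    dplyr::select(inter, locus = "locus_lo", mediator = "locus_hi"),
    dplyr::select(inter, locus = "locus_hi", mediator = "locus_lo")
  ) |> dplyr::distinct()
  # enforce adjacency on locus hulls
  hull <- dplyr::select(loci, "locus_id", "chrom", "start", "end")
  links <- links |>
    dplyr::inner_join(hull, by = c(locus = "locus_id")) |>
    dplyr::inner_join(hull, by = c(mediator = "locus_id"),
                      suffix = c("", ".med")) |>
    dplyr::filter(
      .data$chrom == .data$chrom.med,
      pmax(.data$start, .data$start.med) -
        pmin(.data$end, .data$end.med) <= .env$max_dist
    ) |>
    dplyr::select("locus", "mediator")
  if (nrow(links) == 0) return(empty)
  out <- dplyr::inner_join(
    links, direct, by = c(mediator = "locus_id"),
    relationship = "many-to-many"
  ) |>
    dplyr::transmute(
      locus_id = .data$locus, gene = .data$gene,
      tss_frag = .data$tss_frag, mode = "adjacent",
      mediator_locus = .data$mediator,
      supporting_cell_lines = .data$supporting_cell_lines,
      n_cell_lines = .data$n_cell_lines
    ) |>
    dplyr::arrange(.data$locus_id, .data$gene)
  # a gene already a direct target of the locus is not re-added
  dplyr::anti_join(out, direct, by = c("locus_id", "gene"))
}

#' Nearest gene to a risk SNP
#'
#' A SNP inside a gene's transcript span (`[txStart, txEnd]`, 1-based
#' inclusive) is assigned that gene (rule `within_gene`; ties broken by
#' smallest TSS distance, then gene name). An intergenic SNP gets the gene
#' with the nearest TSS (rule `nearest_tss`). When the nearest gene is
#' non-coding, the nearest protein-coding gene is reported alongside.
#'
#' @param snps Risk-SNP tibble `rsid`, `chrom`, `pos` (1-based).
#' @param genes Gene tibble with `tss` set ([map_tss_to_fragments()] or a
#'   `tss` column).
#' @return Tibble `rsid`, `nearest_gene`, `rule`, `nearest_coding_gene`
#'   (`NA` unless the nearest gene is non-coding).
#' @export
nearest_gene <- function(snps, genes) {
  if (!"tss" %in% names(genes)) {
    genes <- dplyr::mutate(genes, tss = ifelse(.data$strand == "+",
                                               .data$txStart, .data$txEnd))
  }
  purrr::pmap(dplyr::select(snps, "rsid", "chrom", "pos"),
              function(rsid, chrom, pos) {
    g <- genes[genes$chrom == chrom, ]
    if (nrow(g) == 0) stop("no genes on chromosome ", chrom)
    g$tss_dist <- abs(g$tss - pos)
    within <- g[g$txStart <= pos & pos <= g$txEnd, ]
    if (nrow(within) > 0) {
      within <- within[order(within$tss_dist, within$name), ]
      hit <- within[1, ]
      rule <- "within_gene"
    } else {
      g <- g[order(g$tss_dist, g$name), ]
      hit <- g[1, ]
      rule <- "nearest_tss"
    }
    coding <- NA_character_
    if (hit$biotype != "coding") {
      gc <- g[g$biotype == "coding", ]
      if (nrow(gc) > 0) {
        gc <- gc[order(gc$tss_dist, gc$name), ]
        coding <- gc$name[1]
      }
    }
    tibble::tibble(rsid = rsid, nearest_gene = hit$name, rule = rule,
                   nearest_coding_gene = coding)
  }) |> dplyr::bind_rows()
}

#' Compare CHi-C target assignments with the nearest-gene baseline
#'
#' Categorises every risk locus: `uninformative` (no targets), `sole`
#' (the nearest gene of the locus' SNP(s) is the unique target),
#' `one_of_several` (nearest gene among several targets), `other`
#' (targets exist but exclude the nearest gene).
#'
#' @param assignments Combined direct + adjacent target assignments.
#' @param nearest Output of [nearest_gene()].
#' @param loci Locus tibble (risk loci are categorised).
#' @return Tibble `locus_id`, `n_targets`, `nearest_genes` (list),
#'   `category`.
#' @export
compare_chic_vs_nearest <- function(assignments, nearest, loci) {
  risk <- dplyr::filter(loci, .data$is_risk)
  snp_nearest <- setNames(nearest$nearest_gene, nearest$rsid)
  purrr::pmap(dplyr::select(risk, "locus_id", "snp_ids"),
              function(locus_id, snp_ids) {
    targets <- unique(assignments$gene[assignments$locus_id == locus_id])
    near <- unique(unname(snp_nearest[snp_ids]))
    near <- near[!is.na(near)]
    category <- if (length(targets) == 0) {
      "uninformative"
    } else if (any(near %in% targets)) {
      if (length(targets) == 1) "sole" else "one_of_several"
    } else {
      "other"
    }
    tibble::tibble(locus_id = locus_id, n_targets = length(targets),
                   nearest_genes = list(near), category = category)
  }) |> dplyr::bind_rows()
}

#' Hypergeometric enrichment of target genes in a reference gene list
#'
#' Upper-tail probability of observing at least `k` reference genes among
#' the targets when drawing `|targets|` genes from a universe containing
#' `|reference|` reference genes.
#'
#' @param target_genes Character vector of target gene names.
#' @param reference_list Character vector of reference gene names (e.g.
#'   somatically mutated cancer genes).
#' @param universe_size Total number of genes in the universe.
#' @param overlap Optional observed overlap count; defaults to
#'   `length(intersect(target_genes, reference_list))`.
#' @return Tibble `n_targets`, `n_reference`, `overlap`, `p`.
#' @export
enrichment_hypergeometric <- function(target_genes, reference_list,
                                      universe_size, overlap = NULL) {
  n_t <- length(unique(target_genes))
  n_r <- length(unique(reference_list))
  stopifnot(n_t <= universe_size, n_r <= universe_size)
  if (is.null(overlap)) {
    overlap <- length(intersect(unique(target_genes),
                                unique(reference_list)))
  }
  if (overlap > min(n_t, n_r)) {
    stop("overlap exceeds the smaller of the two sets")
  }
  p <- stats::phyper(overlap - 1, n_r, universe_size - n_r, n_t,
                     lower.tail = FALSE)
  tibble::tibble(n_targets = n_t, n_reference = n_r,
                 overlap = overlap, p = p)
}
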