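#' Canonical string key for a fragment pair
#'
#' @param frag_lo,frag_hi Canonical fragment ids (`frag_lo < frag_hi`).
#' @return Character vector `"lo:hi"`.
#' @export
pair_key <- function(frag_lo, frag_hi) {
  stopifnot(all(frag_lo < frag_hi))
  paste(frag_lo, frag_hi, sep = ":")
}

#' Membership (Venn) counts for peak sets across cell lines
#'
#' For every non-empty subset of cell lines, counts the fragment pairs
#' present in exactly those cell lines' peak sets.
#'
#' @param peaksets Named list of character vectors of pair keys
#'   (see [pair_key()]), one per cell line.
#' @return Tibble `members` (cell lines joined by `&`), `n_cells`,
#'   `count`; subsets with zero pairs are included.
#' @export
peak_overlap_sets <- function(peaksets) {
  stopifnot(length(peaksets) >= 2, !is.null(names(peaksets)))
  lines <- names(peaksets)
  keys <- unique(unlist(peaksets))
  member <- vapply(peaksets, function(s) keys %in% s,
                   logical(length(keys)))
  if (length(keys) == 1) member <- matrix(member, nrow = 1)
  signature <- apply(member, 1, function(m) paste(lines[m], collapse = "&"))
  subsets <- unlist(lapply(seq_along(lines), function(k) {
    utils::combn(lines, k, paste, collapse = "&")
  }))
  counts <- table(factor(signature, levels = subsets))
  tibble::tibble(
    members = subsets,
    n_cells = lengths(strsplit(subsets, "&", fixed = TRUE)),
    count = as.integer(counts[subsets])
  )
}

#' Permutation test for excess peak sharing between cell lines
#'
#' Tests whether the observed number of interaction peaks shared by all
#' cell lines (`mode = "all_shared"`), or exclusive to one focal line
#' (`mode = "exclusive"`), exceeds what random peak sets of the same sizes
#' would produce. Each permutation draws, for every cell line, a uniform
#' random subset of its tested-pair universe with the observed peak-set
#' size; `p = (1 + #{permutation statistic >= observed}) / (n_perm + 1)`.
#'
#' @param peaksets Named list of character vectors of peak pair keys.
#' @param universes Named list of character vectors: all pairs tested in
#'   each cell line (each peak set must be a subset of its universe).
#' @param n_perm Number of permutations; default 10000.
#' @param seed Integer seed (mandatory).
#' @param mode `"all_shared"` or `"exclusive"`.
#' @param focal Focal cell line for `mode = "exclusive"`.
#' @return Tibble `mode`, `focal`, `observed`, `perm_mean`, `p`, `n_perm`.
#' @export
permutation_sharing_test <- function(peaksets, universes, n_perm = 1e4,
                                     seed, mode = c("all_shared",
                                                    "exclusive"),
                                     focal = NULL) {
  mode <- match.arg(mode)
  stopifnot(!missing(seed))
  lines <- names(peaksets)
  stopifnot(setequal(lines, names(universes)))
  sizes <- lengths(peaksets[lines])
  for (l in lines) {
    if (!all(peaksets[[l]] %in% universes[[l]])) {
      stop("peak set of ", l, " is not a subset of its universe")
    }
    if (sizes[l] > length(universes[[l]])) {
      stop("peak set of ", l, " larger than its universe")
    }
  }
  if (mode == "exclusive") {
    stopifnot(!is.null(focal), focal %in% lines)
  }
  all_keys <- unique(unlist(universes))
  uni_idx <- lapply(universes[lines], match, table = all_keys)
  stat <- function(sets_idx) {
    if (mode == "all_shared") {
      shared <- Reduce(intersect, sets_idx)
      length(shared)
    } else {
      others <- unlist(sets_idx[setdiff(lines, focal)])
      length(setdiff(sets_idx[[focal]], others))
    }
  }
  observed <- stat(lapply(peaksets[lines], match, table = all_keys))
  perm_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      drawn <- lapply(lines, function(l) {
        uni_idx[[l]][sample.int(length(uni_idx[[l]]), sizes[l])]
      })
      names(drawn) <- lines
      stat(drawn)
    }, numeric(1))
  })
  tibble::tibble(
    mode = mode,
    focal = if (is.null(focal)) NA_character_ else focal,
    observed = observed,
    perm_mean = mean(perm_stats),
    p = (1 + sum(perm_stats >= observed)) / (n_perm + 1),
    n_perm = n_perm
  )
}

#' Jaccard similarity between two peak sets
#'
#' `J = |A intersect B| / |A union B|`; two empty sets give 1 by
#' convention, with a warning.
#'
#' @param set_a,set_b Character vectors of pair keys.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) {
    warning("both sets empty; Jaccard defined as 1 by convention")
    return(1)
  }
  length(intersect(set_a, set_b)) / u
}

#' Jaccard dissimilarity matrix and hierarchical clustering of peak sets
#'
#' Computes pairwise Jaccard dissimilarities (`1 - J`) between cell-line
#' peak sets and clusters them (default average linkage / UPGMA).
#'
#' @param peaksets Named list of character vectors of pair keys.
#' @param linkage Agglomeration method for [stats::hclust()];
#'   default `"average"`.
#' @return List with `dissimilarity` (matrix), `hclust`, and `newick`
#'   (Newick string, present when the `ape` package is installed).
#' @export
jaccard_dendrogram <- function(peaksets, linkage = "average") {
  lines <- names(peaksets)
  stopifnot(length(lines) >= 2)
  d <- matrix(0, length(lines), length(lines),
              dimnames = list(lines, lines))
  for (i in seq_along(lines)) {
    for (j in seq_along(lines)) {
      if (i < j) {
        d[i, j] <- d[j, i] <- 1 - jaccard(peaksets[[i]], peaksets[[j]])
      }
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  nwk <- NULL
  if (requireNamespace("ape", quietly = TRUE)) {
    nwk <- ape::write.tree(ape::as.phylo(hc))
  }
  list(dissimilarity = d, hclust = hc, newick = nwk)
}

#' Non-parametric tests on per-locus peak counts (or distances)
#'
#' Kruskal-Wallis across all cell lines, plus Mann-Whitney U (two-sided;
#' exact when both groups have at most 8 observations, normal
#' approximation with tie correction otherwise) for specified contrasts of
#' cell-line groups (e.g. ER+ vs ER-). Also applicable to per-peak
#' distance distributions.
#'
#' @param values Tibble with a numeric `value` column (e.g. peaks per
#'   locus) and a `cell_line` column.
#' @param groups Named character vector mapping cell line to group label.
#' @param contrasts List of length-2 character vectors of group labels to
#'   compare with Mann-Whitney; default: none.
#' @return Tibble with one row per test: `test`, `contrast`, `statistic`,
#'   `p`.
#' @export
locus_count_tests <- function(values, groups = NULL, contrasts = list()) {
  stopifnot(all(c("value", "cell_line") %in% names(values)))
  if (dplyr::n_distinct(values$cell_line) < 2) {
    stop("need at least two cell lines")
  }
  kw <- stats::kruskal.test(values$value, factor(values$cell_line))
  out <- tibble::tibble(test = "kruskal_wallis", contrast = "all",
                        statistic = unname(kw$statistic), p = kw$p.value)
  if (length(contrasts) > 0) {
    stopifnot(!is.null(groups))
    values$group <- groups[values$cell_line]
    mw <- purrr::map(contrasts, function(ct) {
      a <- values$value[values$group == ct[1]]
      b <- values$value[values$group == ct[2]]
      if (length(a) == 0 || length(b) == 0) {
        stop("empty group in contrast ", paste(ct, collapse = " vs "))
      }
      exact <- length(a) <= 8 && length(b) <= 8
      wt <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = exact, correct = !exact)
      )
      tibble::tibble(test = "mann_whitney",
                     contrast = paste(ct, collapse = " vs "),
                     statistic = unname(wt$statistic), p = wt$p.value)
    })
    out <- dplyr::bind_rows(out, mw)
  }
  out
}
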