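# Small deterministic fixtures built in code.

# Uniformly tiled fragment map: `n` fragments of `width` bp per chromosome.
tiled_fragment_map <- function(chroms, n, width) {
  frags <- lapply(chroms, function(ch) {
    tibble::tibble(start = (seq_len(n) - 1) * width,
                   end = seq_len(n) * width)
  })
  names(frags) <- chroms
  new_fragment_map(frags)
}

# Coarse two-chromosome map for di-tag classification tests:
# chr1 four 2 Mb fragments (ids 1-4), chr2 two 2 Mb fragments (ids 5-6);
# fragments 1 and 2 captured (regions R1, R2).
coarse_map <- function() {
  fm <- tiled_fragment_map(c("chr1", "chr2"), 4, 2e6)
  fm <- fm[!(fm$chrom == "chr2" & fm$start >= 4e6), ]
  fm$frag_id <- seq_len(nrow(fm))
  regions <- tibble::tibble(
    chrom = "chr1", start = c(5e5, 2.5e6), end = c(6e5, 2.6e6),
    region_id = c("R1", "R2")
  )
  list(fragment_map = mark_captured(fm, regions), regions = regions)
}

# Hand-constructed three-cell-line, four-locus, six-gene truth fixture for
# target-gene assignment. All expectations in the tests were derived by
# hand from the assignment rules.
target_fixture <- function() {
  fm <- tiled_fragment_map(c("chr1", "chr2"), 120, 5e4)
  fm <- fm[!(fm$chrom == "chr2" & fm$start >= 1e6), ]  # chr2: 20 fragments
  fm$frag_id <- seq_len(nrow(fm))                      # chr1 1-120, chr2 121-140
  regions <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(1e5, 2.0e6, 5e5, 9e5),
    end = c(2e5, 2.1e6, 6e5, 9.5e5),
    region_id = c("region_A", "region_B", "region_C", "region_D")
  )
  fm <- mark_captured(fm, regions)
  snps <- tibble::tibble(
    rsid = c("rsA", "rsB", "rsC", "rsD"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    pos = c(150001, 2050001, 550001, 925001)
  )
  loci <- define_loci(regions, snps, merge_gap = 0)
  genes <- tibble::tibble(
    name = c("GA1", "GA2", "GN", "GB1", "GF", "GC1"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "-", "+", "+", "+", "+"),
    txStart = c(320001, 950001, 475001, 2060001, 5900001, 725001),
    txEnd = c(400000, 1025000, 480000, 2150000, 5950000, 790000),
    biotype = c("coding", "coding", "noncoding", "coding", "coding",
                "coding")
  )
  peak <- function(cell, lo, hi, cls) {
    tibble::tibble(cell_line = cell, frag_lo = lo, frag_hi = hi,
                   pair_class = cls,
                   distance = fragment_distance(fm, lo, hi),
                   significant = TRUE)
  }
  peaks <- dplyr::bind_rows(
    peak("CL1", 3, 7, "capture_to_cis"),
    peak("CL2", 3, 7, "capture_to_cis"),
    peak("CL1", 4, 21, "capture_to_cis"),
    peak("CL2", 3, 10, "capture_to_cis"),
    peak("CL3", 3, 10, "capture_to_cis"),
    peak("CL1", 42, 60, "capture_to_cis"),
    peak("CL1", 3, 119, "capture_to_cis"),
    peak("CL2", 3, 119, "capture_to_cis"),
    peak("CL2", 4, 41, "within_capture"),
    peak("CL1", 131, 135, "capture_to_cis"),
    peak("CL2", 131, 135, "capture_to_cis"),
    peak("CL3", 131, 135, "capture_to_cis")
  )
  list(fragment_map = fm, capture_regions = regions, risk_snps = snps,
       loci = loci, genes = genes, peaks = peaks)
}

# Independent step-up BH oracle, written directly from the definition:
# p_adj(i) = min_{j: p_(j) >= p_(i)} m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- pmin(1, m * ranked / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force NB upper tail by mass summation.
nb_tail_oracle <- function(y, mu, size) {
  if (y == 0) return(1)
  1 - sum(dnbinom(0:(y - 1), mu = mu, size = size))
}

# Draws from a left-truncated NB by rejection.
rtrunc_nbinom <- function(n, mu, size, t) {
  out <- integer(0)
  while (length(out) < n) {
    x <- rnbinom(2 * n, mu = mu, size = size)
    out <- c(out, x[x >= t])
  }
  out[seq_len(n)]
}
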