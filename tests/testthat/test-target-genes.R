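test_that("TSS mapping respects strand and shared fragments", {
  fx <- target_fixture()
  genes <- map_tss_to_fragments(fx$genes, fx$fragment_map)
  g <- setNames(genes$tss_frag, genes$name)
  expect_equal(unname(g["GA1"]), 7L)    # + strand: txStart in [300k,350k)
  expect_equal(unname(g["GA2"]), 21L)   # - strand: TSS = txEnd
  expect_equal(unname(g["GB1"]), 42L)
  expect_equal(unname(g["GC1"]), 135L)  # chr2 offset ids
  # two genes 200 bp apart share a fragment
  twins <- tibble::tibble(
    name = c("T1", "T2"), chrom = "chr1", strand = "+",
    txStart = c(301001, 301201), txEnd = c(310000, 310000),
    biotype = "coding"
  )
  tm <- map_tss_to_fragments(twins, fx$fragment_map)
  expect_equal(tm$tss_frag[1], tm$tss_frag[2])
  # TSS outside the map is skipped with a warning
  off <- tibble::tibble(name = "OFF", chrom = "chr1", strand = "+",
                        txStart = 9e6, txEnd = 9.1e6, biotype = "coding")
  expect_warning(out <- map_tss_to_fragments(off, fx$fragment_map),
                 "outside the fragment map")
  expect_equal(nrow(out), 0)
})

test_that("direct targets require >= 2 cell lines within 5 Mb", {
  fx <- target_fixture()
  genes <- map_tss_to_fragments(fx$genes, fx$fragment_map)
  direct <- assign_target_genes(fx$peaks, fx$loci, genes,
                                fx$fragment_map)
  key <- paste(direct$locus_id, direct$gene)
  # hand-derived truth: GA1 (CL1+CL2) and GN (CL2+CL3) at locus_1,
  # GC1 (3 lines) at locus_3
  expect_setequal(key, c("locus_1 GA1", "locus_1 GN", "locus_3 GC1"))
  expect_setequal(direct$supporting_cell_lines[
    direct$gene == "GA1"][[1]], c("CL1", "CL2"))
  expect_setequal(direct$supporting_cell_lines[
    direct$gene == "GN"][[1]], c("CL2", "CL3"))
  # GA2: peak in one cell line only -> not a target
  expect_false("GA2" %in% direct$gene)
  # GB1: its TSS fragment interacts in one cell line only
  expect_false("GB1" %in% direct$gene)
  # GF: TSS 5.9 Mb from locus_1 hull (> 5 Mb) despite peaks in 2 lines
  expect_false("GF" %in% direct$gene)
  # the >= 2-line invariant holds on the output
  expect_true(all(direct$n_cell_lines >= 2))
})

test_that("adjacent-locus targets flow through inter-locus peaks", {
  fx <- target_fixture()
  genes <- map_tss_to_fragments(fx$genes, fx$fragment_map)
  direct <- assign_target_genes(fx$peaks, fx$loci, genes,
                                fx$fragment_map)
  adj <- assign_adjacent_locus_targets(fx$peaks, fx$loci, direct,
                                       fx$fragment_map)
  # the single inter-locus peak (4,41) links locus_1 and locus_2 in CL2;
  # locus_2 gains locus_1's direct targets, locus_1 gains nothing
  expect_setequal(paste(adj$locus_id, adj$gene),
                  c("locus_2 GA1", "locus_2 GN"))
  expect_true(all(adj$mode == "adjacent"))
  expect_true(all(adj$mediator_locus == "locus_1"))
  # without the inter-locus peak there are no adjacent assignments
  no_inter <- dplyr::filter(fx$peaks, pair_class != "within_capture")
  adj0 <- assign_adjacent_locus_targets(no_inter, fx$loci, direct,
                                        fx$fragment_map)
  expect_equal(nrow(adj0), 0)
  # loci further apart than the cutoff are never adjacent
  adj_far <- assign_adjacent_locus_targets(fx$peaks, fx$loci, direct,
                                           fx$fragment_map,
                                           max_dist = 1e6)
  expect_equal(nrow(adj_far), 0)
})

test_that("nearest gene follows within-gene then nearest-TSS rules", {
  fx <- target_fixture()
  # rsA and rsB are intergenic -> nearest TSS
  nn <- nearest_gene(fx$risk_snps, fx$genes)
  n <- setNames(nn$nearest_gene, nn$rsid)
  expect_equal(unname(n["rsA"]), "GA1")
  expect_equal(unname(n["rsB"]), "GB1")
  expect_equal(unname(n["rsC"]), "GC1")
  expect_true(all(nn$rule == "nearest_tss"))
  # a SNP inside a transcript span takes that gene
  inside <- tibble::tibble(rsid = "rsIn", chrom = "chr1", pos = 960000)
  hit <- nearest_gene(inside, fx$genes)
  expect_equal(hit$nearest_gene, "GA2")
  expect_equal(hit$rule, "within_gene")
  # nearest gene non-coding -> nearest coding gene also reported
  near_nc <- tibble::tibble(rsid = "rsNc", chrom = "chr1", pos = 474000)
  out_nc <- nearest_gene(near_nc, fx$genes)
  expect_equal(out_nc$nearest_gene, "GN")
  expect_equal(out_nc$nearest_coding_gene, "GA1")
  expect_error(
    nearest_gene(tibble::tibble(rsid = "x", chrom = "chrZ", pos = 1),
                 fx$genes),
    "no genes on chromosome"
  )
})

test_that("agreement categories cover every risk locus exactly once", {
  fx <- target_fixture()
  genes <- map_tss_to_fragments(fx$genes, fx$fragment_map)
  direct <- assign_target_genes(fx$peaks, fx$loci, genes,
                                fx$fragment_map)
  adj <- assign_adjacent_locus_targets(fx$peaks, fx$loci, direct,
                                       fx$fragment_map)
  assignments <- dplyr::bind_rows(direct, adj)
  nn <- nearest_gene(fx$risk_snps, fx$genes)
  agr <- compare_chic_vs_nearest(assignments, nn, fx$loci)
  cat_by <- setNames(agr$category, agr$locus_id)
  # locus_1: targets {GA1, GN}, nearest GA1 -> one of several
  expect_equal(unname(cat_by["locus_1"]), "one_of_several")
  # locus_2: targets {GA1, GN} (adjacent), nearest GB1 -> other
  expect_equal(unname(cat_by["locus_2"]), "other")
  # locus_3: sole target GC1 is the nearest gene
  expect_equal(unname(cat_by["locus_3"]), "sole")
  # locus_4: no peaks anywhere -> uninformative
  expect_equal(unname(cat_by["locus_4"]), "uninformative")
  expect_equal(nrow(agr), sum(fx$loci$is_risk))
})

test_that("hypergeometric enrichment matches direct combinatorics", {
  # universe 10, reference 5, targets 2, overlap 2: C(5,2)/C(10,2) = 10/45
  out <- enrichment_hypergeometric(c("g1", "g2"), paste0("r", 1:5), 10,
                                   overlap = 2)
  expect_equal(out$p, choose(5, 2) / choose(10, 2), tolerance = 1e-12)
  # zero overlap -> p = 1
  expect_equal(
    enrichment_hypergeometric(c("a", "b"), c("c", "d"), 100)$p, 1)
  # reference equals the universe -> certainty
  expect_equal(
    enrichment_hypergeometric(paste0("g", 1:3), paste0("g", 1:10), 10,
                              overlap = 3)$p, 1)
  expect_error(
    enrichment_hypergeometric(c("a"), c("b"), 10, overlap = 5),
    "overlap exceeds"
  )
})
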