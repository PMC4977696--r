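# the generator: determinism, realized rates, downstream consistency

test_that("generate_cluster_genome is deterministic and respects its contract", {
  g1 <- generate_cluster_genome(seed = 77L)
  g2 <- generate_cluster_genome(seed = 77L)
  expect_identical(g1$record$residues, g2$record$residues)
  expect_identical(g1$truth, g2$truth)
  expect_equal(length(g1$annotation$genes), 12L)
  # genes sorted, inside the core, and all translatable
  starts <- vapply(g1$annotation$genes, `[[`, 0L, "start")
  expect_true(all(diff(starts) > 0))
  expect_gte(min(starts), g1$truth$core_interval[["start"]])
  prots <- bgccompare:::.translate_cluster(g1$cluster)
  expect_length(prots, 12L)
  # exactly one NRPS-like megagene
  lens <- vapply(g1$annotation$genes, function(g) g$end - g$start, 0L)
  expect_equal(sum(lens > 15000L), 1L)
  # minimal case
  g3 <- generate_cluster_genome(n_genes = 2L, gene_len_range = c(300L, 300L),
                                nrps_len = NULL, flank_len = 100L,
                                intergenic_len_range = c(50L, 50L), seed = 5L)
  expect_length(bgccompare:::.translate_cluster(g3$cluster), 2L)
  expect_error(generate_cluster_genome(gene_len_range = c(3L, 6L), seed = 1L),
               "impossible")
})

test_that("default core lengths land in the 45-60 kb range (8 seeds)", {
  # spot-check of the stated property at reduced seed count for runtime
  for (s in seq(101L, 136L, by = 5L)) {
    g <- generate_cluster_genome(seed = s)
    expect_gte(g$truth$core_len, 45000L)
    expect_lte(g$truth$core_len, 60000L)
  }
})

test_that("evolve_sequence: identity accounting and determinism", {
  base <- random_record(50000L, 9L, "base")
  ev0 <- evolve_sequence(base, sub_rate = 0, indel_rate = 0,
                         ambiguity_rate = 0, seed = 1L)
  expect_equal(ev0$record$residues, base$residues)
  ev1 <- evolve_sequence(base, sub_rate = 0.11, seed = 2L)
  ev1b <- evolve_sequence(base, sub_rate = 0.11, seed = 2L)
  expect_identical(ev1$record$residues, ev1b$record$residues)
  # realized identity within the binomial band around 0.89
  expect_equal(ev1$truth$realized_identity, 0.89, tolerance = 0.01 / 0.89)
  expect_equal(1 - length(ev1$truth$substitution_positions) / 50000L,
               ev1$truth$realized_identity)
  expect_error(evolve_sequence(base, sub_rate = 0.4, indel_rate = 0.2, seed = 1L),
               "below 0.5")
})

test_that("logged ambiguity sites classify as 'ambiguity' downstream", {
  base <- random_record(4000L, 10L, "base")
  ev <- evolve_sequence(base, ambiguity_rate = 0.01, seed = 3L)
  aln <- global_align_nt(base, ev$record)
  cc <- classify_columns(aln)
  # no indels: columns map 1:1 to positions
  cols <- ev$truth$ambiguity_positions + 1L
  expect_true(all(cc$classes[cols] == "ambiguity"))
  expect_equal(cc$ambiguity, length(cols))
})

test_that("protect_orfs keeps evolved genes translatable and lifts coordinates", {
  g <- small_cluster(88L)
  ev <- evolve_sequence(g$record, sub_rate = 0.10, indel_rate = 5e-4,
                        protect_orfs = TRUE, annotation = g$annotation,
                        seed = 89L)
  prots <- suppressWarnings(bgccompare:::.translate_cluster(
    annotated_cluster(ev$record, ev$annotation)))
  expect_length(prots, 5L)
  # lifted genes still start with ATG (up to planted substitutions, which
  # protect only against stop creation, so check length multiple of 3)
  for (gm in ev$annotation$genes) {
    expect_equal((gm$end - gm$start) %% 3L, 0L)
  }
})

test_that("split_with_overlap honours its contract", {
  rec <- random_record(3000L, 12L, "cl")
  sp0 <- split_with_overlap(rec, 1500L, overlap_len = 200L,
                            overlap_divergence = 0, seed = 1L)
  # zero divergence: left suffix equals right prefix exactly
  expect_equal(substr(sp0$left$residues, 1501L, 1700L),
               substr(sp0$right$residues, 1L, 200L))
  expect_equal(nchar(sp0$left$residues), 1700L)
  expect_equal(nchar(sp0$right$residues), 1500L)
  sp1 <- split_with_overlap(rec, 1500L, overlap_len = 200L,
                            overlap_divergence = 0.04, seed = 2L)
  expect_equal(sp1$truth$realized_overlap_identity,
               1 - sp1$truth$n_overlap_substitutions / 200L)
  expect_error(split_with_overlap(rec, 100L, overlap_len = 200L, seed = 1L),
               "junction")
})

test_that("splitting through a gene still reassembles to an intact ORF", {
  g <- small_cluster(23L)
  mid_gene <- g$annotation$genes[[3L]]
  junction <- (mid_gene$start + mid_gene$end) %/% 2L
  sp <- split_with_overlap(g$record, junction, overlap_len = 200L,
                           overlap_divergence = 0.03, seed = 24L)
  merged <- merge_contigs(find_best_overlap(list(sp$left, sp$right)),
                          sp$left, sp$right)
  # ORF-scan oracle: the reassembled gene translates cleanly again
  prot_orig <- translate_cds(g$record, mid_gene)
  prot_back <- translate_cds(merged$record, mid_gene)
  expect_equal(prot_back$residues, prot_orig$residues)
})

test_that("fixtures are deterministic, written to disk, and self-described", {
  expect_error(make_comparison_fixture("nope", seed = 1L),
               "ani_vs_ae.*ecd_hty_reassembly.*marker_panel.*two_clade_msa")
  d <- withr::local_tempdir()
  fx <- make_comparison_fixture("marker_panel", seed = 31L, dir = d)
  fx2 <- make_comparison_fixture("marker_panel", seed = 31L)
  expect_identical(fx$markers[[2L]]$residues, fx2$markers[[2L]]$residues)
  expect_true(file.exists(file.path(d, "markers.fasta")))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$its_differences, 1L)
  d2 <- withr::local_tempdir()
  make_comparison_fixture("two_clade_msa", seed = 31L, dir = d2)
  expect_true(file.exists(file.path(d2, "msa.fasta")))
  expect_true(file.exists(file.path(d2, "truth.json")))
})
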