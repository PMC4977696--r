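# window profiles, core delimitation, inconsistency/marker/group counting

test_that("window tiling follows the partial-window rule", {
  full <- manual_alignment(strrep("A", 500L), strrep("A", 500L))
  prof <- window_identity_profile(full, 50L)
  expect_equal(nrow(prof), 10L)
  expect_true(all(prof$identity == 1))
  expect_true(all(prof$class == "full"))
  expect_equal(prof$col_start, seq(1L, 451L, by = 50L))
  expect_equal(prof$col_end, seq(50L, 500L, by = 50L))
  # 520 columns: remainder 20 < 25 merges into the last window (70 columns)
  prof2 <- window_identity_profile(manual_alignment(strrep("A", 520L),
                                                    strrep("A", 520L)), 50L)
  expect_equal(nrow(prof2), 10L)
  expect_equal(prof2$col_end[10L] - prof2$col_start[10L] + 1L, 70L)
  # 530 columns: remainder 30 >= 25 stays its own window
  prof3 <- window_identity_profile(manual_alignment(strrep("A", 530L),
                                                    strrep("A", 530L)), 50L)
  expect_equal(nrow(prof3), 11L)
  # alignment shorter than half a window -> single window
  prof4 <- window_identity_profile(manual_alignment("ACGTACGTACGT", "ACGTACGTACGT"), 50L)
  expect_equal(nrow(prof4), 1L)
  expect_error(window_identity_profile(full, 5L), ">= 10")
})

test_that("window identities equal direct per-window recomputation", {
  withr::with_seed(31L, {
    a <- random_record(1234L, 31L, "a")
    b <- random_record(1200L, 32L, "b")
    aln <- global_align_nt(a, b)
    prof <- window_identity_profile(aln, 50L)
    ac <- strsplit(aln$a_gapped, "")[[1L]]
    bc <- strsplit(aln$b_gapped, "")[[1L]]
    for (w in seq_len(nrow(prof))) {
      idx <- prof$col_start[w]:prof$col_end[w]
      direct <- mean(ac[idx] == bc[idx] & ac[idx] != "-")
      expect_equal(prof$identity[w], direct)
    }
    expect_equal(prof$col_start[-1L], prof$col_end[-nrow(prof)] + 1L)  # tiling
  })
})

test_that("detect_core_boundaries finds runs, tolerates dips, errors when absent", {
  core <- detect_core_boundaries(manual_profile(c(0.3, 0.3, 0.9, 0.9, 0.9, 0.3)))
  expect_equal(c(core$window_start, core$window_end), c(3L, 5L))
  expect_gt(core$mean_core_identity, core$mean_flank_identity)
  # whole-alignment core
  all_high <- detect_core_boundaries(manual_profile(rep(0.95, 8L)))
  expect_equal(c(all_high$window_start, all_high$window_end), c(1L, 8L))
  expect_true(is.na(all_high$mean_flank_identity))
  # an interior dip of <= max_low_run windows >= t_low is bridged
  dip <- detect_core_boundaries(manual_profile(c(0.2, 0.9, 0.9, 0.5, 0.9, 0.2)))
  expect_equal(c(dip$window_start, dip$window_end), c(2L, 5L))
  # a dip below t_low splits the run
  split <- detect_core_boundaries(manual_profile(c(0.9, 0.9, 0.9, 0.1, 0.9, 0.2)))
  expect_equal(c(split$window_start, split$window_end), c(1L, 3L))
  expect_error(detect_core_boundaries(manual_profile(rep(0.3, 5L))), "no core")
})

test_that("core detection mirrors under alignment reversal", {
  withr::with_seed(77L, {
    flank1 <- random_dna_str(600L)
    flank2 <- random_dna_str(600L)
    core_seq <- random_dna_str(1800L)
    a <- seq_record("a", paste0(flank1, core_seq, flank2))
    mut <- strsplit(core_seq, "")[[1L]]
    pos <- sample(1800L, 150L)
    for (p in pos) mut[p] <- sample(setdiff(c("A", "C", "G", "T"), mut[p]), 1L)
    b <- seq_record("b", paste0(random_dna_str(600L),
                                paste(mut, collapse = ""), random_dna_str(600L)))
    aln <- global_align_nt(a, b)
    L <- nchar(aln$a_gapped)
    Luse <- 50L * (L %/% 50L)   # truncate to a multiple of the window for symmetry
    fwd <- manual_alignment(substr(aln$a_gapped, 1L, Luse),
                            substr(aln$b_gapped, 1L, Luse))
    strrev <- function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = "")
    rev_aln <- manual_alignment(strrev(fwd$a_gapped), strrev(fwd$b_gapped))
    cf <- detect_core_boundaries(window_identity_profile(fwd, 50L))
    cr <- detect_core_boundaries(window_identity_profile(rev_aln, 50L))
    nw <- Luse %/% 50L
    expect_equal(cr$window_start, nw - cf$window_end + 1L)
    expect_equal(cr$window_end, nw - cf$window_start + 1L)
  })
})

test_that("count_genuine_inconsistencies separates substitutions from gaps", {
  same <- manual_alignment("ACGTACGT", "ACGTACGT")
  expect_equal(count_genuine_inconsistencies(same)$count, 0L)
  mixed <- manual_alignment("ACGT", "A-GA")
  got <- count_genuine_inconsistencies(mixed)
  expect_equal(got$count, 1L)
  expect_equal(got$positions, 4L)
})

test_that("marker_diff counts basepair differences like the barcode convention", {
  fx <- make_comparison_fixture("marker_panel", seed = 21L)
  m <- fx$markers
  expect_equal(marker_diff(m[[1L]], m[[2L]])$genuine_substitution,
               fx$truth$its_differences)
  expect_equal(marker_diff(m[[3L]], m[[4L]])$genuine_substitution,
               fx$truth$cam_differences)
  d3 <- marker_diff(m[[5L]], m[[6L]])
  expect_equal(d3$genuine_substitution, fx$truth$indel_differences)
  expect_equal(d3$gap, fx$truth$indel_gap_columns)
  # identical markers
  expect_equal(marker_diff(m[[1L]], seq_record("copy", m[[1L]]$residues))$genuine_substitution, 0L)
})

test_that("conserved_group_differences applies the unanimity rule", {
  rows <- c(a1 = "ACGT", a2 = "ACGT", b1 = "ACGA", b2 = "ACGA")
  got <- conserved_group_differences(rows, c("a1", "a2"), c("b1", "b2"))
  expect_equal(got$count, 1L)
  expect_equal(got$columns, 4L)
  # polymorphism within a group disqualifies the column
  rows2 <- c(a1 = "ACGT", a2 = "ACGC", b1 = "ACGA", b2 = "ACGA")
  expect_equal(conserved_group_differences(rows2, c("a1", "a2"), c("b1", "b2"))$count, 0L)
  # gaps and ambiguity codes never support a conserved difference
  rows3 <- c(a1 = "A-RT", a2 = "A-RT", b1 = "G-AA", b2 = "G-AA")
  got3 <- conserved_group_differences(rows3, c("a1", "a2"), c("b1", "b2"))
  expect_equal(got3$columns, c(1L, 4L))
  expect_error(conserved_group_differences(c(a = "ACG", b = "AC"), "a", "b"),
               "length mismatch")
  expect_error(conserved_group_differences(rows, c("a1", "b1"), c("b1", "b2")),
               "disjoint")
})

test_that("align_star produces consistent rows usable for group counting", {
  recs <- list(seq_record("r1", "ACGTACGTACGT"),
               seq_record("r2", "ACGTACCGTACGT"),  # 1 bp insertion
               seq_record("r3", "ACGTACGTACGT"))
  rows <- align_star(recs)
  expect_equal(length(unique(nchar(rows))), 1L)
  expect_equal(gsub("-", "", rows[["r2"]]), "ACGTACCGTACGT")
  expect_equal(gsub("-", "", rows[["r1"]]), "ACGTACGTACGT")
})

test_that("two-clade fixture yields exactly its planted diagnostic columns", {
  for (s in c(2L, 14L)) {
    fx <- make_comparison_fixture("two_clade_msa", seed = s)
    got <- conserved_group_differences(fx$rows, fx$truth$group_a, fx$truth$group_b)
    expect_equal(got$count, fx$truth$n_diagnostic)
    expect_equal(got$columns, fx$truth$diagnostic_columns)
  }
})
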