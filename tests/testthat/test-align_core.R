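# alignment engines vs the independent full-matrix DP oracle, identity
# policies, and column classification

test_that("global nucleotide alignment: forced small examples", {
  x <- random_record(100L, 1L, "x")
  same <- seq_record("y", x$residues)
  aln <- global_align_nt(x, same)
  expect_equal(aln$score, 200)                  # 100 matches at +2
  expect_equal(classify_columns(aln)$genuine_substitution, 0L)
  aln2 <- global_align_nt(seq_record("a", "ACGT"), seq_record("b", "ACGA"))
  cc <- classify_columns(aln2)
  expect_equal(cc$match, 3L)
  expect_equal(cc$genuine_substitution, 1L)
  expect_error(global_align_nt(seq_record("p", "MK", alphabet = "protein"), x),
               "non-nucleotide")
})

test_that("nucleotide aligner matches the full-matrix DP oracle on random pairs", {
  S <- nt_substitution_matrix()
  withr::with_seed(42L, {
    for (i in 1:60) {
      a <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1L), TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1L), TRUE), collapse = "")
      got <- global_align_nt(seq_record("a", a), seq_record("b", b))
      expect_equal(got$score, oracle_affine_score(a, b, S, -18, -6))
      # alignment invariant: stripping gaps reproduces the inputs
      expect_equal(gsub("-", "", got$a_gapped), a)
      expect_equal(gsub("-", "", got$b_gapped), b)
    }
  })
})

test_that("protein aligner matches the DP oracle and handles trivial cases", {
  p <- seq_record("p", strrep("ACDEF", 4L), alphabet = "protein")
  aln <- global_align_aa(p, seq_record("q", p$residues, alphabet = "protein"))
  expect_equal(percent_identity(aln, "exclude_gap_columns"), 1.0)
  cc <- classify_columns(global_align_aa(
    seq_record("a", "MK", alphabet = "protein"),
    seq_record("b", "ML", alphabet = "protein")))
  expect_equal(cc$match, 1L)
  expect_equal(cc$genuine_substitution, 1L)
  S <- bgccompare:::get_protein_matrix("BLOSUM62")
  aas <- rownames(S)[1:20]
  withr::with_seed(7L, {
    for (i in 1:40) {
      a <- paste(sample(aas, sample(5:30, 1L), TRUE), collapse = "")
      b <- paste(sample(aas, sample(5:30, 1L), TRUE), collapse = "")
      got <- global_align_aa(seq_record("a", a, alphabet = "protein"),
                             seq_record("b", b, alphabet = "protein"))
      expect_equal(got$score, oracle_affine_score(a, b, S, -11, -1))
    }
  })
  expect_error(global_align_aa(seq_record("n", "ACGT"), p), "non-protein")
})

test_that("overlap_align finds suffix-prefix overlaps and spans them", {
  aln <- overlap_align(seq_record("a", "AAAACGTG"), seq_record("b", "ACGTGTTT"))
  expect_equal(aln$a_gapped, "ACGTG")
  expect_equal(aln$b_gapped, "ACGTG")
  expect_equal(aln$a_start, 3L); expect_equal(aln$a_end, 8L)
  expect_equal(aln$b_start, 0L); expect_equal(aln$b_end, 5L)
  expect_equal(percent_identity(aln), 1.0)
})

test_that("overlap_align recovers planted overlaps (property, 30 seeded trials)", {
  ok <- 0L
  for (s in 1:30) {
    parts <- withr::with_seed(s, list(
      x = random_dna_str(sample(200:600, 1L)),
      shared = random_dna_str(sample(50:150, 1L)),
      y = random_dna_str(sample(200:600, 1L))))
    a <- seq_record("a", paste0(parts$x, parts$shared))
    b <- seq_record("b", paste0(parts$shared, parts$y))
    aln <- overlap_align(a, b)
    # recovered overlap must contain the planted shared span
    if (aln$a_start <= nchar(parts$x) &&
        aln$b_end >= nchar(parts$shared)) ok <- ok + 1L
  }
  expect_gte(ok, 30L)
})

test_that("overlap identity of unrelated sequences never passes merge thresholds", {
  # scaled empirical null: 40 random pairs, 500 bp each
  for (s in 1:40) {
    a <- random_record(500L, 1000L + s, "a")
    b <- random_record(500L, 2000L + s, "b")
    aln <- overlap_align(a, b)
    len <- min(aln$a_end - aln$a_start, aln$b_end - aln$b_start)
    passes <- len >= 100L && percent_identity(aln) >= 0.90
    expect_false(passes)
  }
})

test_that("percent_identity policies give the forced arithmetic", {
  aln <- manual_alignment("ACGTACGTAC", "ACGTAC--AA")
  expect_equal(percent_identity(aln, "all_columns"), 0.70)
  expect_equal(percent_identity(aln, "exclude_gap_columns"), 0.875)
  ident <- manual_alignment("ACGT", "ACGT")
  for (p in c("all_columns", "exclude_gap_columns", "exclude_gap_and_ambiguity")) {
    expect_equal(percent_identity(ident, p), 1.0)
  }
})

test_that("a 53.9 kb-scale alignment with 3 genuine substitutions reads ~99.99 %", {
  # matches + gaps + ambiguities everywhere except 3 genuine substitutions
  n <- 53900L
  a <- strrep("A", n)
  bc <- rep("A", n)
  bc[c(1000L, 25000L, 50000L)] <- "G"          # genuine
  bc[seq(2000L, 2039L)] <- "-"                 # 40 gap columns
  bc[seq(3000L, 3011L)] <- "R"                 # 12 compatible ambiguities
  aln <- manual_alignment(a, paste(bc, collapse = ""))
  expect_equal(percent_identity(aln, "exclude_gap_and_ambiguity"),
               (n - 3L - 40L) / n)
  expect_gt(percent_identity(aln, "exclude_gap_and_ambiguity"), 0.9990)
  expect_equal(count_genuine_inconsistencies(aln)$count, 3L)
})

test_that("classify_columns follows IUPAC set logic and the class priority", {
  aln <- manual_alignment("AARRN-A", "AACR-TC")
  cc <- classify_columns(aln)
  # cols: A/A match, A/A match, R/C genuine, R/R ambiguity, N/- gap,
  #       -/T gap, A/C genuine
  expect_equal(cc$match, 2L)
  expect_equal(cc$genuine_substitution, 2L)
  expect_equal(cc$gap, 2L)
  expect_equal(cc$ambiguity, 1L)
  expect_error(classify_columns(manual_alignment("AZ", "AA")),
               "non-nucleotide|non-IUPAC")
})

test_that("classification matches a brute-force per-column oracle on random data", {
  alpha <- c("A", "C", "G", "T", "R", "Y", "N", "-")
  withr::with_seed(99L, {
    for (rep in 1:5) {
      n <- 1000L
      ac <- sample(alpha, n, TRUE, prob = c(rep(0.22, 4), 0.04, 0.04, 0.02, 0.02))
      bc <- sample(alpha, n, TRUE, prob = c(rep(0.22, 4), 0.04, 0.04, 0.02, 0.02))
      both_gap <- ac == "-" & bc == "-"
      ac[both_gap] <- "A"                       # no all-gap columns
      a <- paste(ac, collapse = ""); b <- paste(bc, collapse = "")
      got <- classify_columns(manual_alignment(a, b))
      want <- oracle_classify(a, b)
      expect_equal(got$match, unname(want[["match"]]))
      expect_equal(got$genuine_substitution, unname(want[["genuine_substitution"]]))
      expect_equal(got$gap, unname(want[["gap"]]))
      expect_equal(got$ambiguity, unname(want[["ambiguity"]]))
      expect_equal(got$match + got$genuine_substitution + got$gap + got$ambiguity,
                   nchar(a))                    # conservation
    }
  })
})

test_that("percent_identity is invariant under swapping alignment rows", {
  withr::with_seed(5L, {
    for (rep in 1:10) {
      a <- random_record(300L, rep, "a")
      b <- random_record(300L, rep + 100L, "b")
      aln <- global_align_nt(a, b)
      swapped <- manual_alignment(aln$b_gapped, aln$a_gapped)
      for (p in c("all_columns", "exclude_gap_columns", "exclude_gap_and_ambiguity")) {
        expect_equal(percent_identity(aln, p), percent_identity(swapped, p))
      }
    }
  })
})

test_that("anchored mode agrees with direct expectations on long sequences", {
  # identical 8 kb sequences force the anchored path; identity must be 1
  x <- random_record(8000L, 12L, "x")
  aln <- global_align_nt(x, seq_record("y", x$residues))
  expect_equal(percent_identity(aln), 1.0)
  expect_equal(nchar(aln$a_gapped), 8000L)
  # 20 planted substitutions, widely separated
  chars <- strsplit(x$residues, "")[[1L]]
  pos <- seq(200L, by = 390L, length.out = 20L)
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1L]
  aln2 <- global_align_nt(x, seq_record("y", paste(chars, collapse = "")))
  expect_equal(count_genuine_inconsistencies(aln2)$count, 20L)
  expect_equal(percent_identity(aln2), (8000 - 20) / 8000)
})
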