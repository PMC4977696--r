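# ortholog mapping, collinearity, identity matrices

# two small diverged clusters, built once per file
ga <- small_cluster(501L, id = "clusterA")
gb <- diverged_cluster(ga, sub_rate = 0.08, seed = 502L, id = "clusterB")

test_that("identical clusters pair every gene with itself at identity 1", {
  twin <- ga$cluster
  twin$record <- seq_record("clusterA2", ga$record$residues)
  twin$annotation$seq_id <- "clusterA2"
  twin <- annotated_cluster(twin$record, twin$annotation)
  tab <- map_orthologs(ga$cluster, twin)
  expect_equal(nrow(tab$pairs), 5L)
  expect_equal(tab$pairs$gene_a, tab$pairs$gene_b)
  expect_true(all(tab$pairs$identity == 1))
  expect_length(tab$unpaired_a, 0L)
})

test_that("a gene missing from one cluster lands in unpaired_a", {
  missing <- gb$cluster
  keep <- missing$annotation$genes[-3L]
  missing <- annotated_cluster(missing$record,
                               cluster_annotation(missing$record$id, keep))
  tab <- map_orthologs(ga$cluster, missing)
  expect_equal(nrow(tab$pairs), 4L)
  expect_equal(tab$unpaired_a, "g03")
})

test_that("diverged orthologs are all recovered as reciprocal best hits", {
  tab <- map_orthologs(ga$cluster, gb$cluster)
  expect_equal(nrow(tab$pairs), 5L)
  expect_equal(tab$pairs$gene_a, tab$pairs$gene_b)   # generator keeps ids
  # nucleotide sub rate 0.08 -> protein identity far above noise, below 1
  expect_true(all(tab$pairs$identity > 0.7 & tab$pairs$identity < 1))
  # symmetry: roles swap cleanly
  rev_tab <- map_orthologs(gb$cluster, ga$cluster)
  expect_equal(rev_tab$pairs$gene_a, tab$pairs$gene_b)
  expect_equal(rev_tab$pairs$identity, tab$pairs$identity)
})

# annotations with five genes in a chosen physical order of orthologs
perm_annotation <- function(id, order_of_pairs) {
  genes <- lapply(seq_along(order_of_pairs), function(i) {
    gene_model(sprintf("g%02d", order_of_pairs[i]),
               (i - 1L) * 1000L, (i - 1L) * 1000L + 300L, "+")
  })
  cluster_annotation(id, genes)
}

perm_table <- function(n = 5L) {
  structure(list(cluster_a = "A", cluster_b = "B",
                 pairs = data.frame(gene_a = sprintf("g%02d", 1:n),
                                    gene_b = sprintf("g%02d", 1:n),
                                    identity = rep(0.9, n),
                                    stringsAsFactors = FALSE),
                 unpaired_a = character(), unpaired_b = character()),
            class = "ortholog_table")
}

test_that("collinearity detects preserved, reversed and broken orders", {
  a <- perm_annotation("A", 1:5)
  same <- check_collinearity(perm_table(), a, perm_annotation("B", 1:5))
  expect_true(same$collinear)
  expect_equal(same$breakpoints, 0L)
  rev_ <- check_collinearity(perm_table(), a, perm_annotation("B", 5:1))
  expect_true(rev_$collinear)                      # orientation normalization
  expect_equal(rev_$orientation, "reverse")
  swapped <- check_collinearity(perm_table(), a, perm_annotation("B", c(1, 3, 2, 4, 5)))
  expect_false(swapped$collinear)
  expect_equal(swapped$breakpoints, 1L)
  expect_error(check_collinearity(
    structure(list(pairs = perm_table()$pairs[1L, ]), class = "ortholog_table"),
    a, a), "insufficient")
})

test_that("breakpoint counts match the exhaustive descent oracle", {
  withr::with_seed(11L, {
    for (rep in 1:20) {
      perm <- sample(6L)
      rep_ <- check_collinearity(perm_table(6L), perm_annotation("A", 1:6),
                                 perm_annotation("B", perm))
      inv <- order(perm)    # B-rank sequence in A order
      expect_equal(rep_$breakpoints,
                   min(oracle_descents(inv), oracle_descents(rev(inv))))
    }
  })
})

test_that("collinearity verdict is invariant under strand flip of one cluster", {
  b_fwd <- perm_annotation("B", c(2, 1, 3, 4, 5))
  # mirror the B cluster: reverse physical order and flip strands
  total <- 5000L
  genes_rev <- lapply(b_fwd$genes, function(g) {
    gene_model(g$gene_id, total - g$end, total - g$start,
               if (g$strand == "+") "-" else "+")
  })
  b_rev <- cluster_annotation("B", genes_rev)
  a <- perm_annotation("A", 1:5)
  r1 <- check_collinearity(perm_table(), a, b_fwd)
  r2 <- check_collinearity(perm_table(), a, b_rev)
  expect_equal(r1$collinear, r2$collinear)
  expect_equal(r1$breakpoints, r2$breakpoints)
})

test_that("identity_matrix has the reference-by-cluster structure", {
  twin <- annotated_cluster(seq_record("twin", ga$record$residues),
                            cluster_annotation("twin", ga$annotation$genes))
  clusters <- list(ref = ga$cluster, twin = twin, far = gb$cluster)
  M <- identity_matrix(clusters, "ref")
  expect_equal(rownames(M), sprintf("g%02d", 1:5))
  expect_equal(colnames(M), c("twin", "far"))
  expect_true(all(M[, "twin"] == 100))
  expect_true(all(M[, "far"] < 100 & M[, "far"] > 50))
  # absent ortholog -> NA cell
  dropped <- annotated_cluster(gb$cluster$record,
                               cluster_annotation(gb$cluster$record$id,
                                                  gb$cluster$annotation$genes[-2L]))
  M2 <- identity_matrix(list(ref = ga$cluster, d = dropped), "ref")
  expect_true(is.na(M2["g02", "d"]))
  expect_error(identity_matrix(clusters, "nope"), "not in cluster list")
})

test_that("identity matrix cells are monotone with planted divergence", {
  near <- diverged_cluster(ga, sub_rate = 0.02, seed = 601L, id = "near")
  far <- diverged_cluster(ga, sub_rate = 0.15, seed = 602L, id = "far")
  M <- identity_matrix(list(ref = ga$cluster, near = near$cluster,
                            far = far$cluster), "ref")
  expect_true(all(M[, "near"] > M[, "far"]))
})

test_that("overall_identity: symmetry, unit diagonal, concatenation algebra", {
  near <- diverged_cluster(ga, sub_rate = 0.05, seed = 603L, id = "near")
  clusters <- list(A = ga$cluster, B = near$cluster, C = gb$cluster)
  M <- overall_identity(clusters)
  expect_equal(diag(unclass(M)), c(A = 1, B = 1, C = 1))
  expect_equal(M[lower.tri(M)], t(M)[lower.tri(M)])
  expect_true(M["A", "B"] > M["A", "C"])           # planted divergence order
  # algebraic oracle: concatenated identity == non-gap-column-weighted mean
  prots_a <- bgccompare:::.translate_cluster(ga$cluster)
  prots_b <- bgccompare:::.translate_cluster(near$cluster)
  ids <- attr(M, "proteins")
  num <- 0; den <- 0
  for (g in ids) {
    aln <- global_align_aa(prots_a[[g]], prots_b[[g]])
    cc <- classify_columns(aln)
    nongap <- nchar(aln$a_gapped) - cc$gap
    num <- num + percent_identity(aln, "exclude_gap_columns") * nongap
    den <- den + nongap
  }
  expect_equal(M["A", "B"], num / den, tolerance = 1e-12)
  # error contract: no universally shared protein
  # a poly-glycine ORF shares no credible orthology with any cluster protein
  polyg <- paste0("ATG", strrep("GGT", 120L), "TAA")
  empty_b <- annotated_cluster(
    seq_record("E", polyg),
    cluster_annotation("E", list(gene_model("zz", 0L, nchar(polyg), "+"))))
  expect_error(overall_identity(list(A = ga$cluster, E = empty_b)),
               "no protein occurs in all clusters")
})
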