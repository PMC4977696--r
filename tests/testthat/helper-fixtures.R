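# shared small-fixture builders (everything generated in code; no data files)

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_record <- function(n, seed, id = sprintf("rnd%d", seed)) {
  withr::with_seed(seed, seq_record(id, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")))
}

# a small annotated cluster (fast to generate/align): 5 genes, no megagene
small_cluster <- function(seed, id = NULL) {
  g <- generate_cluster_genome(n_genes = 5L, gene_len_range = c(300L, 900L),
                               nrps_len = NULL,
                               intergenic_len_range = c(50L, 200L),
                               flank_len = 500L, seed = seed)
  if (!is.null(id)) {
    g$record$id <- id
    g$annotation$seq_id <- id
    g$cluster <- annotated_cluster(g$record, g$annotation)
  }
  g
}

# diverged copy of a small cluster with translatable genes preserved
diverged_cluster <- function(g, sub_rate, seed, id) {
  ev <- evolve_sequence(g$record, sub_rate = sub_rate, indel_rate = 1e-4,
                        ambiguity_rate = 0, protect_orfs = TRUE,
                        annotation = g$annotation, seed = seed)
  rec <- ev$record; rec$id <- id
  ann <- ev$annotation; ann$seq_id <- id
  list(cluster = annotated_cluster(rec, ann), truth = ev$truth)
}

# hand-built alignment object for forced-arithmetic examples
manual_alignment <- function(a_gapped, b_gapped, alphabet = "nucleotide") {
  bgccompare:::new_pairwise_alignment(
    "a", "b", a_gapped, b_gapped, NA_real_,
    0L, nchar(gsub("-", "", a_gapped)),
    0L, nchar(gsub("-", "", b_gapped)), alphabet)
}

# window profile object from bare identity values (window size 50)
manual_profile <- function(identities, window_size = 50L) {
  n <- length(identities)
  structure(data.frame(col_start = seq.int(1L, by = window_size, length.out = n),
                       col_end = seq.int(window_size, by = window_size, length.out = n),
                       identity = identities,
                       class = ifelse(identities == 1, "full",
                                      ifelse(identities < 0.30, "low", "partial")),
                       stringsAsFactors = FALSE),
            class = c("window_profile", "data.frame"),
            window_size = window_size,
            match_indicator = NULL)
}
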