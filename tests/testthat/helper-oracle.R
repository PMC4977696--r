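# Independent oracles, deliberately written without reusing any package
# internals: a full-matrix affine-gap DP (score only) and a per-column
# brute-force classifier with its own copy of the IUPAC tables.

oracle_affine_score <- function(a, b, S, gap_open, gap_extend) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e30
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1L, j + 1L] <- gap_open + j * gap_extend
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- S[A[i], B[j]]
    M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open + gap_extend,
                             X[i, j + 1L] + gap_extend,
                             Y[i, j + 1L] + gap_open + gap_extend)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open + gap_extend,
                             X[i + 1L, j] + gap_open + gap_extend,
                             Y[i + 1L, j] + gap_extend)
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_classify_column <- function(ca, cb) {
  if (ca == "-" || cb == "-") return("gap")
  sa <- ORACLE_IUPAC[[ca]]; sb <- ORACLE_IUPAC[[cb]]
  ambiguous <- length(sa) > 1L || length(sb) > 1L
  if (ambiguous && length(intersect(sa, sb)) > 0L) return("ambiguity")
  if (!ambiguous && ca == cb) return("match")
  "genuine_substitution"
}

oracle_classify <- function(a_gapped, b_gapped) {
  ac <- strsplit(a_gapped, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b_gapped, "", fixed = TRUE)[[1L]]
  table(factor(mapply(oracle_classify_column, ac, bc),
               levels = c("match", "genuine_substitution", "gap", "ambiguity")))
}

# exhaustive descent count of a permutation (collinearity oracle)
oracle_descents <- function(perm) {
  n <- 0L
  for (i in seq_len(length(perm) - 1L)) if (perm[i + 1L] < perm[i]) n <- n + 1L
  n
}
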