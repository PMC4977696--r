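# IUPAC nucleotide codes and compatibility logic.
#
# Two codes are "compatible" when their base sets intersect (R vs A: yes;
# R vs C: no). This is the test used both for alignment-column triage
# (ambiguity vs genuine substitution) and, as a scoring choice, to let
# ambiguity codes attract rather than repel their compatible bases during
# alignment.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

NT_ALPHABET <- names(IUPAC_SETS)
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X")

# 15 x 15 logical matrix: do the base sets of two IUPAC codes intersect?
IUPAC_COMPAT <- local({
  n <- length(IUPAC_SETS)
  m <- matrix(FALSE, n, n, dimnames = list(NT_ALPHABET, NT_ALPHABET))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- length(intersect(IUPAC_SETS[[i]], IUPAC_SETS[[j]])) > 0
  }
  m
})

is_ambiguity_code <- function(x) {
  x %in% NT_ALPHABET & !(x %in% c("A", "C", "G", "T"))
}

#' Nucleotide substitution matrix over the IUPAC alphabet
#'
#' Builds the scoring matrix used by the nucleotide aligners. Any pair of
#' codes whose base sets intersect scores `match`; all other pairs score
#' `mismatch`. Scoring compatible ambiguities as matches keeps ambiguity
#' sites from distorting gap placement, consistent with their later triage
#' as non-genuine differences.
#'
#' @param match match score (default +2)
#' @param mismatch mismatch score (default -3)
#' @return a 15 x 15 numeric matrix with IUPAC row/column names
#' @export
nt_substitution_matrix <- function(match = 2, mismatch = -3) {
  S <- matrix(mismatch, length(NT_ALPHABET), length(NT_ALPHABET),
              dimnames = list(NT_ALPHABET, NT_ALPHABET))
  S[IUPAC_COMPAT] <- match
  S
}

# cached BLOSUM-style protein matrices from Biostrings
.matrix_cache <- new.env(parent = emptyenv())

get_protein_matrix <- function(name = "BLOSUM62") {
  if (!is.null(.matrix_cache[[name]])) return(.matrix_cache[[name]])
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || is.null(env[[name]])) {
    stop("unknown substitution matrix: ", name)
  }
  M <- env[[name]]
  keep <- intersect(AA_ALPHABET, rownames(M))
  M <- M[keep, keep, drop = FALSE]
  .matrix_cache[[name]] <- M
  M
}
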