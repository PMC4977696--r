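# Pairwise alignment engines and alignment-column accounting.
#
# All aligners share one affine-gap dynamic-programming core (src/align.cpp)
# with the gap convention: a gap of length L costs gap_open + L*gap_extend.
# Traceback ties break diagonal > up > left, so alignments are reproducible.
#
# Inputs up to 5 kb x 5 kb are aligned by full-matrix DP (optimal); longer
# inputs go through an anchored mode (see align_anchor.R) that is exact
# between exact-match anchors.

FULL_DP_MAX_CELLS <- 25e6   # 5 kb x 5 kb

# Gap costs are calibrated so that the optimal global alignment of
# unrelated DNA reads ~30 % identity (the baseline cluster-comparison
# figures show for flanking regions); cheaper gaps let the DP harvest
# spurious matches in unrelated sequence and push that baseline near 50 %,
# which would blur the core/flank contrast the boundary detector relies on.
default_nt_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = -18, gap_extend = -6)
}

new_pairwise_alignment <- function(a_id, b_id, a_gapped, b_gapped, score,
                                   a_start, a_end, b_start, b_end, alphabet) {
  stopifnot(nchar(a_gapped) == nchar(b_gapped))
  structure(list(a_id = a_id, b_id = b_id,
                 a_gapped = a_gapped, b_gapped = b_gapped, score = score,
                 a_start = a_start, a_end = a_end,
                 b_start = b_start, b_end = b_end,
                 alphabet = alphabet),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s[%d,%d) vs %s[%d,%d): %d columns, score %.1f\n",
              x$a_id, x$a_start, x$a_end, x$b_id, x$b_start, x$b_end,
              nchar(x$a_gapped), x$score))
  invisible(x)
}

alignment_ncol <- function(aln) nchar(aln$a_gapped)

# per-column character vectors of the two rows
alignment_rows <- function(aln) {
  list(a = strsplit(aln$a_gapped, "", fixed = TRUE)[[1L]],
       b = strsplit(aln$b_gapped, "", fixed = TRUE)[[1L]])
}

# 0-based position in the ungapped a (b) sequence for each column's residue;
# NA at gap columns
alignment_coords <- function(aln) {
  rows <- alignment_rows(aln)
  a_pos <- ifelse(rows$a == "-", NA_integer_, cumsum(rows$a != "-")) + aln$a_start - 1L
  b_pos <- ifelse(rows$b == "-", NA_integer_, cumsum(rows$b != "-")) + aln$b_start - 1L
  list(a = as.integer(a_pos), b = as.integer(b_pos))
}

.encode <- function(residues, alphabet_chars, what) {
  idx <- match(strsplit(residues, "", fixed = TRUE)[[1L]], alphabet_chars)
  if (anyNA(idx)) stop("non-", what, " character in sequence")
  idx - 1L  # 0-based for C++
}

.decode_alignment <- function(a_res, b_res, fit, a_id, b_id, alphabet) {
  ac <- strsplit(a_res, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b_res, "", fixed = TRUE)[[1L]]
  arow <- ifelse(fit$a_idx == 0L, "-", ac[pmax(fit$a_idx, 1L)])
  brow <- ifelse(fit$b_idx == 0L, "-", bc[pmax(fit$b_idx, 1L)])
  new_pairwise_alignment(a_id, b_id,
                         paste(arow, collapse = ""), paste(brow, collapse = ""),
                         fit$score,
                         as.integer(fit$a_start), as.integer(fit$a_end),
                         as.integer(fit$b_start), as.integer(fit$b_end),
                         alphabet)
}

.check_nt_pair <- function(a, b) {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"))
  if (a$alphabet != "nucleotide" || b$alphabet != "nucleotide") {
    stop("nucleotide aligner called on non-nucleotide input")
  }
}

#' Global nucleotide alignment
#'
#' Optimal affine-gap global (Needleman-Wunsch) alignment for inputs whose
#' DP matrix fits in 5 kb x 5 kb; longer inputs are aligned in anchored
#' mode: unique shared 15-mers are chained collinearly and the regions
#' between anchors are aligned optimally. End-to-end coverage of both
#' sequences is guaranteed in both modes.
#'
#' @param a,b nucleotide `seq_record`s
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (defaults +2/-3/-18/-6; the gap costs keep unrelated DNA near the
#'   ~30 % identity baseline, see the methods vignette)
#' @return a `pairwise_alignment`
#' @export
global_align_nt <- function(a, b, scoring = default_nt_scoring()) {
  .check_nt_pair(a, b)
  S <- nt_substitution_matrix(scoring$match, scoring$mismatch)
  na <- seq_len_record(a); nb <- seq_len_record(b)
  if (as.double(na) * nb > FULL_DP_MAX_CELLS) {
    return(align_anchored(a, b, S, scoring$gap_open, scoring$gap_extend,
                          alphabet = "nucleotide"))
  }
  fit <- .affine_align_cpp(.encode(a$residues, NT_ALPHABET, "IUPAC"),
                           .encode(b$residues, NT_ALPHABET, "IUPAC"),
                           S, scoring$gap_open, scoring$gap_extend,
                           FALSE, FALSE, FALSE, FALSE)
  .decode_alignment(a$residues, b$residues, fit, a$id, b$id, "nucleotide")
}

#' Global protein alignment
#'
#' Optimal affine-gap global alignment under a log-odds substitution matrix
#' (default BLOSUM62, gap open -11, gap extend -1). Very long proteins
#' (DP beyond 5 kb x 5 kb residues) use the anchored mode.
#'
#' @param a,b protein `seq_record`s
#' @param matrix substitution matrix name known to Biostrings (e.g.
#'   `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`)
#' @param gap_open,gap_extend affine gap scores
#' @return a `pairwise_alignment`
#' @export
global_align_aa <- function(a, b, matrix = "BLOSUM62",
                            gap_open = -11, gap_extend = -1) {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"))
  if (a$alphabet != "protein" || b$alphabet != "protein") {
    stop("protein aligner called on non-protein input")
  }
  S <- get_protein_matrix(matrix)
  alpha <- rownames(S)
  na <- seq_len_record(a); nb <- seq_len_record(b)
  if (as.double(na) * nb > FULL_DP_MAX_CELLS) {
    return(align_anchored(a, b, S, gap_open, gap_extend, alphabet = "protein"))
  }
  fit <- .affine_align_cpp(.encode(a$residues, alpha, "matrix-alphabet"),
                           .encode(b$residues, alpha, "matrix-alphabet"),
                           S, gap_open, gap_extend, FALSE, FALSE, FALSE, FALSE)
  .decode_alignment(a$residues, b$residues, fit, a$id, b$id, "protein")
}

#' Suffix-prefix (free-end-gap) overlap alignment
#'
#' Aligns a suffix of the first sequence to a prefix of the second:
#' skipping a prefix of `suffix_of` and a suffix of `prefix_of` is
#' unpenalized, so the optimum delimits the overlap, whose span
#' coordinates are returned. Only the terminal `max_search` bases of each
#' contig enter the DP (contigs can be tens of kb; the overlap of interest
#' is a few hundred bp), which bounds runtime without affecting overlaps
#' shorter than `max_search`.
#'
#' @param suffix_of contig whose suffix overlaps
#' @param prefix_of contig whose prefix overlaps
#' @param scoring as in [global_align_nt()]
#' @param max_search terminal window entered into the DP (bp, default 5000)
#' @return a `pairwise_alignment` spanning the overlap
#' @export
overlap_align <- function(suffix_of, prefix_of, scoring = default_nt_scoring(),
                          max_search = 5000L) {
  .check_nt_pair(suffix_of, prefix_of)
  na <- seq_len_record(suffix_of); nb <- seq_len_record(prefix_of)
  a_off <- max(0L, na - as.integer(max_search))
  a_win <- substr(suffix_of$residues, a_off + 1L, na)
  b_win <- substr(prefix_of$residues, 1L, min(nb, as.integer(max_search)))
  S <- nt_substitution_matrix(scoring$match, scoring$mismatch)
  fit <- .affine_align_cpp(.encode(a_win, NT_ALPHABET, "IUPAC"),
                           .encode(b_win, NT_ALPHABET, "IUPAC"),
                           S, scoring$gap_open, scoring$gap_extend,
                           TRUE, FALSE, FALSE, TRUE)
  aln <- .decode_alignment(a_win, b_win, fit, suffix_of$id, prefix_of$id,
                           "nucleotide")
  aln$a_start <- aln$a_start + a_off
  aln$a_end <- aln$a_end + a_off
  aln
}

#' Percent identity of an alignment
#'
#' Three published-style policies are exposed:
#' \describe{
#'   \item{all_columns}{matches / total columns (default; gap and ambiguity
#'     columns count as non-matching).}
#'   \item{exclude_gap_columns}{matches / columns without a gap.}
#'   \item{exclude_gap_and_ambiguity}{(matches + compatible-ambiguity
#'     columns) / total columns — only genuine substitutions count against
#'     identity.}
#' }
#'
#' @param aln a `pairwise_alignment`
#' @param policy identity policy (see Details)
#' @return a fraction in `[0, 1]`
#' @export
percent_identity <- function(aln, policy = c("all_columns", "exclude_gap_columns",
                                             "exclude_gap_and_ambiguity")) {
  policy <- match.arg(policy)
  cc <- classify_columns(aln)
  total <- alignment_ncol(aln)
  denom <- switch(policy,
                  all_columns = total,
                  exclude_gap_columns = total - cc$gap,
                  exclude_gap_and_ambiguity = total)
  if (denom == 0L) stop("zero denominator under policy '", policy, "'")
  num <- switch(policy,
                all_columns = cc$match,
                exclude_gap_columns = cc$match,
                exclude_gap_and_ambiguity = cc$match + cc$ambiguity)
  num / denom
}

#' Classify alignment columns
#'
#' Each column receives exactly one class, by priority
#' gap > ambiguity > match > genuine_substitution:
#' \itemize{
#'   \item \strong{gap}: `-` in exactly one row;
#'   \item \strong{ambiguity}: no gap, at least one residue is an IUPAC
#'     ambiguity code, and the two codes' base sets intersect (R vs A);
#'   \item \strong{match}: identical unambiguous residues;
#'   \item \strong{genuine_substitution}: everything else, including
#'     incompatible ambiguity codes (R vs C).
#' }
#' For protein alignments only gap/match/substitution apply.
#'
#' @param aln a `pairwise_alignment`
#' @return a `site_class_counts` with fields `match`,
#'   `genuine_substitution`, `gap`, `ambiguity` and a `classes` character
#'   vector (one entry per column)
#' @export
classify_columns <- function(aln) {
  rows <- alignment_rows(aln)
  classes <- .classify_chars(rows$a, rows$b, aln$alphabet)
  counts <- table(factor(classes, levels = c("match", "genuine_substitution",
                                             "gap", "ambiguity")))
  structure(list(match = unname(counts[["match"]]),
                 genuine_substitution = unname(counts[["genuine_substitution"]]),
                 gap = unname(counts[["gap"]]),
                 ambiguity = unname(counts[["ambiguity"]]),
                 classes = classes),
            class = "site_class_counts")
}

.classify_chars <- function(ac, bc, alphabet = "nucleotide") {
  gap <- xor(ac == "-", bc == "-")
  if (any(ac == "-" & bc == "-")) stop("all-gap column in alignment")
  if (alphabet == "nucleotide") {
    known <- c(NT_ALPHABET, "-")
    bad <- which(!(ac %in% known) | !(bc %in% known))
    if (length(bad)) stop("non-IUPAC character at column ", bad[1L])
    ia <- match(ac, NT_ALPHABET); ib <- match(bc, NT_ALPHABET)
    compat <- !gap & IUPAC_COMPAT[cbind(ia, ib)]
    amb <- compat & (is_ambiguity_code(ac) | is_ambiguity_code(bc))
    match_ <- !gap & !amb & ac == bc
  } else {
    amb <- rep(FALSE, length(ac))
    match_ <- !gap & ac == bc
  }
  ifelse(gap, "gap",
         ifelse(amb, "ambiguity",
                ifelse(match_, "match", "genuine_substitution")))
}

#' @export
print.site_class_counts <- function(x, ...) {
  cat(sprintf("<site_class_counts> match %d | substitution %d | gap %d | ambiguity %d (total %d)\n",
              x$match, x$genuine_substitution, x$gap, x$ambiguity,
              x$match + x$genuine_substitution + x$gap + x$ambiguity))
  invisible(x)
}

#' Export an alignment as aligned FASTA
#'
#' @param aln a `pairwise_alignment`
#' @param path output path
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0(">", aln$a_id), aln$a_gapped,
               paste0(">", aln$b_id), aln$b_gapped), con)
  invisible(path)
}

#' Export a per-column class report as TSV
#'
#' Columns: `column` (1-based), `a_residue`, `b_residue`, `class`.
#'
#' @param aln a `pairwise_alignment`
#' @param path output path
#' @param classes_only restrict rows to non-match columns
#' @export
write_column_report <- function(aln, path, classes_only = TRUE) {
  rows <- alignment_rows(aln)
  cc <- classify_columns(aln)
  df <- data.frame(column = seq_along(cc$classes),
                   a_residue = rows$a, b_residue = rows$b,
                   class = cc$classes, stringsAsFactors = FALSE)
  if (classes_only) df <- df[df$class != "match", , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# score an existing gapped alignment under the same affine convention
score_gapped <- function(a_gapped, b_gapped, S, gap_open, gap_extend) {
  ac <- strsplit(a_gapped, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b_gapped, "", fixed = TRUE)[[1L]]
  alpha <- rownames(S)
  gap_a <- ac == "-"; gap_b <- bc == "-"
  sub_cols <- !gap_a & !gap_b
  sc <- sum(S[cbind(match(ac[sub_cols], alpha), match(bc[sub_cols], alpha))])
  # affine gap runs in either row
  runs <- function(g) {
    if (!any(g)) return(c(0L, 0L))
    r <- rle(g)
    c(sum(r$values), sum(r$lengths[r$values]))  # n_runs, total_len
  }
  ra <- runs(gap_a); rb <- runs(gap_b)
  sc + (ra[1L] + rb[1L]) * gap_open + (ra[2L] + rb[2L]) * gap_extend
}
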