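# Suffix-prefix overlap detection between subcluster contigs, merging into
# one continuous sequence with per-position provenance, and verification of
# the merge against a reference cluster. This is the stage that corrects a
# split-cluster misassembly: two contigs that share a terminal overlap (a
# few hundred bp at high identity) are fused into a single cluster sequence.

#' Find the best terminal overlap among contigs
#'
#' Evaluates every ordered contig pair in all four orientation
#' combinations with [overlap_align()] and keeps hits whose overlap spans
#' at least `min_len` bp in both contigs at `all_columns` identity >=
#' `min_identity`. Among passing hits the one maximizing
#' identity x min(overlap lengths) wins. Unrelated contigs essentially
#' never pass the default thresholds (random DNA aligns near 30-50 %
#' identity over short stretches only).
#'
#' @param contigs list of >= 2 nucleotide `seq_record`s
#' @param min_len minimal overlap length in each contig (bp, default 100)
#' @param min_identity minimal `all_columns` identity (default 0.90)
#' @param scoring as in [global_align_nt()]
#' @param max_search terminal window searched per contig (bp)
#' @return an `overlap_hit`, or `NULL` if no hit passes
#' @export
find_best_overlap <- function(contigs, min_len = 100L, min_identity = 0.90,
                              scoring = default_nt_scoring(),
                              max_search = 5000L) {
  if (length(contigs) < 2L) stop("need at least 2 contigs")
  oriented <- function(rec, orientation) {
    if (orientation == "forward") rec else {
      rc <- revcomp(rec); rc$id <- rec$id; rc
    }
  }
  best <- NULL; best_rank <- -Inf
  idx <- seq_along(contigs)
  for (i in idx) for (j in idx) {
    if (i == j) next
    for (oa in c("forward", "revcomp")) for (ob in c("forward", "revcomp")) {
      a <- oriented(contigs[[i]], oa)
      b <- oriented(contigs[[j]], ob)
      aln <- overlap_align(a, b, scoring, max_search)
      len_a <- aln$a_end - aln$a_start
      len_b <- aln$b_end - aln$b_start
      if (min(len_a, len_b) < min_len) next
      ident <- percent_identity(aln, "all_columns")
      if (ident < min_identity) next
      rank <- ident * min(len_a, len_b)
      if (rank > best_rank) {
        best_rank <- rank
        best <- structure(list(left_id = contigs[[i]]$id,
                               right_id = contigs[[j]]$id,
                               left_orientation = oa, right_orientation = ob,
                               overlap_len_left = len_a,
                               overlap_len_right = len_b,
                               overlap_columns = alignment_ncol(aln),
                               identity = ident,
                               alignment = aln,
                               min_len = min_len, min_identity = min_identity),
                          class = "overlap_hit")
      }
    }
  }
  best
}

#' @export
print.overlap_hit <- function(x, ...) {
  cat(sprintf("<overlap_hit> %s(%s) -> %s(%s): %d columns (%d/%d bp), identity %.4f\n",
              x$left_id, x$left_orientation, x$right_id, x$right_orientation,
              x$overlap_columns, x$overlap_len_left, x$overlap_len_right,
              x$identity))
  invisible(x)
}

#' Merge two contigs across a detected overlap
#'
#' Produces left-unique prefix + overlap consensus + right-unique suffix.
#' Within the overlap, matching columns emit the shared base; a column
#' with a gap in one row emits the present base; conflicting residue
#' columns are resolved by `conflict_policy` (`prefer_unambiguous`, the
#' default, takes the unambiguous residue when exactly one side is an
#' IUPAC ambiguity code and otherwise falls back to the left contig).
#' Per-position provenance (`left` / `consensus` / `right`) and the
#' junction range (0-based half-open, in merged coordinates) are recorded.
#'
#' @param hit an `overlap_hit` referring to these contigs
#' @param left,right the contig `seq_record`s named in the hit
#' @param conflict_policy `"prefer_unambiguous"`, `"prefer_left"` or
#'   `"prefer_right"`
#' @return a `merged_sequence`: list with `record`, `junction`,
#'   `provenance`, `conflicts`
#' @export
merge_contigs <- function(hit, left, right,
                          conflict_policy = c("prefer_unambiguous",
                                              "prefer_left", "prefer_right")) {
  conflict_policy <- match.arg(conflict_policy)
  stopifnot(inherits(hit, "overlap_hit"))
  if (hit$left_id != left$id || hit$right_id != right$id) {
    stop("hit refers to contigs '", hit$left_id, "'/'", hit$right_id, "'")
  }
  if (min(hit$overlap_len_left, hit$overlap_len_right) < hit$min_len ||
      hit$identity < hit$min_identity) {
    stop("overlap hit violates its own thresholds")
  }
  if (hit$left_orientation == "revcomp") { left <- revcomp(left); left$id <- hit$left_id }
  if (hit$right_orientation == "revcomp") { right <- revcomp(right); right$id <- hit$right_id }
  aln <- hit$alignment
  rows <- alignment_rows(aln)
  amb_a <- is_ambiguity_code(rows$a)
  amb_b <- is_ambiguity_code(rows$b)
  cons <- character(length(rows$a))
  conflicts <- 0L
  for (k in seq_along(rows$a)) {
    ca <- rows$a[k]; cb <- rows$b[k]
    if (ca == cb) { cons[k] <- ca; next }
    if (ca == "-") { cons[k] <- cb; next }
    if (cb == "-") { cons[k] <- ca; next }
    conflicts <- conflicts + 1L
    cons[k] <- switch(conflict_policy,
                      prefer_left = ca,
                      prefer_right = cb,
                      prefer_unambiguous = {
                        if (amb_a[k] && !amb_b[k]) cb
                        else if (amb_b[k] && !amb_a[k]) ca
                        else ca
                      })
  }
  consensus <- paste(cons, collapse = "")
  prefix <- substr(left$residues, 1L, aln$a_start)
  suffix <- substr(right$residues, aln$b_end + 1L, seq_len_record(right))
  residues <- paste0(prefix, consensus, suffix)
  provenance <- c(rep("left", nchar(prefix)),
                  rep("consensus", nchar(consensus)),
                  rep("right", nchar(suffix)))
  junction <- c(start = nchar(prefix), end = nchar(prefix) + nchar(consensus))
  record <- seq_record(paste0(left$id, "+", right$id), residues,
                       alphabet = "nucleotide",
                       description = sprintf("merged via %d-column overlap",
                                             alignment_ncol(aln)))
  structure(list(record = record, junction = junction,
                 provenance = provenance, conflicts = conflicts,
                 hit = hit),
            class = "merged_sequence")
}

#' @export
print.merged_sequence <- function(x, ...) {
  cat(sprintf("<merged_sequence> %s: %d bp, junction [%d, %d), %d conflict(s)\n",
              x$record$id, seq_len_record(x$record),
              x$junction[["start"]], x$junction[["end"]], x$conflicts))
  invisible(x)
}

#' Verify a merged sequence against a reference cluster
#'
#' Globally aligns the merged sequence to a reference and reports the
#' full-length `all_columns` identity, the windowed identity profile and
#' the genuine-inconsistency count — the quantities by which a reassembled
#' cluster is compared to an independently deposited one.
#'
#' @param merged a `merged_sequence` or nucleotide `seq_record`
#' @param reference a nucleotide `seq_record`
#' @param window_size profile window (columns)
#' @param scoring as in [global_align_nt()]
#' @return list with `identity`, `profile`, `inconsistencies`, `alignment`
#' @export
reference_verify <- function(merged, reference, window_size = 50L,
                             scoring = default_nt_scoring()) {
  rec <- if (inherits(merged, "merged_sequence")) merged$record else merged
  aln <- global_align_nt(rec, reference, scoring)
  profile <- window_identity_profile(aln, window_size)
  inc <- count_genuine_inconsistencies(aln)
  list(identity = percent_identity(aln, "all_columns"),
       profile = profile,
       inconsistencies = inc$count,
       inconsistency_positions = inc$positions,
       alignment = aln)
}

#' Write merge provenance as BED
#'
#' One BED interval per provenance run over the merged sequence
#' (0-based half-open, as BED requires).
#'
#' @param merged a `merged_sequence`
#' @param path output path
#' @export
write_provenance_bed <- function(merged, path) {
  r <- rle(merged$provenance)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  df <- data.frame(chrom = merged$record$id, start = starts, end = ends,
                   name = r$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
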