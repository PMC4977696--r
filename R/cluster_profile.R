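# Windowed identity profiles, conserved-core delimitation, and
# inconsistency / marker / group-difference counting.
#
# Alignment columns are numbered 1-based; windows and the core interval are
# 1-based inclusive column ranges. (Sequence coordinates elsewhere in the
# package remain 0-based half-open.)

#' Sliding-window identity profile of an alignment
#'
#' Tiles the alignment with non-overlapping windows in alignment-column
#' space and computes per-window identity under the `all_columns` policy.
#' A final partial window is kept if it holds at least half a window of
#' columns, else it is merged into the previous window. Windows are
#' classed `full` (identity == 1), `low` (identity < 0.30) or `partial`
#' otherwise, mirroring the three colour classes used in published cluster
#' identity plots (100 %, 30-<100 %, <30 %).
#'
#' @param aln a `pairwise_alignment`
#' @param window_size columns per window (>= 10; default 50)
#' @return a `window_profile`: data.frame with `col_start`, `col_end`
#'   (1-based inclusive), `identity`, `class`; the per-column match
#'   indicator is kept as attribute `match_indicator`
#' @export
window_identity_profile <- function(aln, window_size = 50L) {
  window_size <- as.integer(window_size)
  if (window_size < 10L) stop("window_size must be >= 10")
  cc <- classify_columns(aln)
  m <- as.integer(cc$classes == "match")
  L <- length(m)
  k <- L %/% window_size
  rem <- L %% window_size
  if (k == 0L) {
    starts <- 1L; ends <- L
  } else if (rem == 0L) {
    starts <- seq.int(1L, by = window_size, length.out = k)
    ends <- starts + window_size - 1L
  } else if (rem >= window_size / 2) {
    starts <- seq.int(1L, by = window_size, length.out = k + 1L)
    ends <- c(starts[-1L] - 1L, L)
  } else {
    starts <- seq.int(1L, by = window_size, length.out = k)
    ends <- c(starts[-1L] - 1L, L)   # last window absorbs the remainder
  }
  csum <- c(0L, cumsum(m))
  identity <- (csum[ends + 1L] - csum[starts]) / (ends - starts + 1L)
  class <- ifelse(identity == 1, "full", ifelse(identity < 0.30, "low", "partial"))
  out <- data.frame(col_start = starts, col_end = ends,
                    identity = identity, class = class,
                    stringsAsFactors = FALSE)
  structure(out, class = c("window_profile", "data.frame"),
            window_size = window_size, match_indicator = m)
}

#' Delimit the conserved core of a windowed profile
#'
#' Finds the maximal contiguous run of windows with identity >=
#' `t_high`, tolerating interior interruptions of at most `max_low_run`
#' consecutive windows provided these stay >= `t_low`. This captures the
#' published pattern of a conserved cluster core whose windowed identity
#' drops abruptly to the unrelated-sequence baseline (~30 %) at both ends.
#' Boundaries are reported at window resolution plus refined column
#' positions where a 50-column running mean of the match indicator crosses
#' the midpoint `(t_high + t_low) / 2`.
#'
#' @param profile a `window_profile`
#' @param t_high identity a window must reach to seed/extend the core
#' @param t_low identity an interior interruption may not fall below
#' @param max_low_run maximal interior interruption length, in windows
#' @return a `core_interval`: list with `col_start`, `col_end` (1-based
#'   inclusive), `window_start`, `window_end` (window indices),
#'   `refined_col_start`, `refined_col_end`, `mean_core_identity`,
#'   `mean_flank_identity` (NA when the core spans the whole profile)
#' @export
detect_core_boundaries <- function(profile, t_high = 0.60, t_low = 0.40,
                                   max_low_run = 2L) {
  stopifnot(inherits(profile, "window_profile"), nrow(profile) > 0L)
  id <- profile$identity
  high <- which(id >= t_high)
  if (!length(high)) stop("no core detected: no window reaches t_high = ", t_high)
  # merge high windows into runs allowing bounded, not-too-low interruptions
  run_start <- high[1L]; run_end <- high[1L]
  best <- c(run_start, run_end)
  for (h in high[-1L]) {
    gap_idx <- if (h - run_end > 1L) (run_end + 1L):(h - 1L) else integer()
    if (length(gap_idx) <= max_low_run && all(id[gap_idx] >= t_low)) {
      run_end <- h
    } else {
      if (run_end - run_start > best[2L] - best[1L]) best <- c(run_start, run_end)
      run_start <- h; run_end <- h
    }
  }
  if (run_end - run_start > best[2L] - best[1L]) best <- c(run_start, run_end)
  ws <- best[1L]; we <- best[2L]
  col_start <- profile$col_start[ws]
  col_end <- profile$col_end[we]
  core_windows <- ws:we
  flank_windows <- setdiff(seq_len(nrow(profile)), core_windows)
  mean_core <- mean(id[core_windows])
  mean_flank <- if (length(flank_windows)) mean(id[flank_windows]) else NA_real_
  # sub-window refinement via a 50-column running mean of the match indicator
  m <- attr(profile, "match_indicator")
  mid <- (t_high + t_low) / 2
  span <- 50L
  refined_start <- col_start; refined_end <- col_end
  if (!is.null(m) && length(m) >= span) {
    csum <- c(0, cumsum(m))
    fwd_ok <- function(c0) {
      e <- min(c0 + span - 1L, length(m))
      (csum[e + 1L] - csum[c0]) / (e - c0 + 1L) >= mid
    }
    cand <- col_start:min(profile$col_end[ws], length(m))
    hit <- cand[vapply(cand, fwd_ok, TRUE)]
    if (length(hit)) refined_start <- hit[1L]
    bwd_ok <- function(c0) {
      s <- max(c0 - span + 1L, 1L)
      (csum[c0 + 1L] - csum[s]) / (c0 - s + 1L) >= mid
    }
    cand <- profile$col_start[we]:col_end
    hit <- cand[vapply(cand, bwd_ok, TRUE)]
    if (length(hit)) refined_end <- hit[length(hit)]
  }
  structure(list(col_start = col_start, col_end = col_end,
                 window_start = ws, window_end = we,
                 refined_col_start = refined_start,
                 refined_col_end = refined_end,
                 mean_core_identity = mean_core,
                 mean_flank_identity = mean_flank),
            class = "core_interval")
}

#' @export
print.core_interval <- function(x, ...) {
  cat(sprintf("<core_interval> columns %d-%d (windows %d-%d); core identity %.3f, flank %.3f\n",
              x$col_start, x$col_end, x$window_start, x$window_end,
              x$mean_core_identity,
              if (is.na(x$mean_flank_identity)) NA else x$mean_flank_identity))
  invisible(x)
}

#' Count genuinely inconsistent columns
#'
#' A genuine inconsistency is an alignment column where both sequences
#' carry unambiguous, different bases — as opposed to gap columns and
#' compatible IUPAC-ambiguity columns, which are discounted.
#'
#' @param aln a nucleotide `pairwise_alignment`
#' @return list with `count` and `positions` (1-based alignment columns,
#'   ascending)
#' @export
count_genuine_inconsistencies <- function(aln) {
  cc <- classify_columns(aln)
  pos <- which(cc$classes == "genuine_substitution")
  list(count = length(pos), positions = pos)
}

#' Base-pair differences between two marker sequences
#'
#' Globally aligns two marker sequences (e.g. ITS or calmodulin barcodes)
#' and classifies the columns; the headline "basepair difference" count of
#' strain-discrimination work is the `genuine_substitution` field.
#'
#' @param a,b nucleotide `seq_record`s
#' @param scoring as in [global_align_nt()]
#' @return a `site_class_counts`
#' @export
marker_diff <- function(a, b, scoring = default_nt_scoring()) {
  classify_columns(global_align_nt(a, b, scoring))
}

#' Group-conserved differences in a multiple alignment
#'
#' Counts columns where every group-A row shares one unambiguous, non-gap
#' residue, every group-B row shares one unambiguous, non-gap residue, and
#' the two residues differ — the "species-conserved difference" criterion
#' used to discriminate close taxa. Columns polymorphic within a group
#' never count.
#'
#' @param aligned_rows named character vector (or named list) of
#'   equal-length gapped sequences
#' @param group_a,group_b disjoint, non-empty sets of row names
#' @return list with `count` and `columns` (1-based)
#' @export
conserved_group_differences <- function(aligned_rows, group_a, group_b) {
  rows <- unlist(aligned_rows)
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) stop("rows must be named")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (!length(group_a) || !length(group_b)) stop("each group needs >= 1 row")
  missing <- setdiff(c(group_a, group_b), names(rows))
  if (length(missing)) stop("unknown row ids: ", paste(missing, collapse = " "))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) stop("row length mismatch")
  mat <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  rownames(mat) <- names(rows)
  fixed_residue <- function(col) {
    u <- unique(col)
    if (length(u) == 1L && u != "-" && !is_ambiguity_code(u)) u else NA_character_
  }
  ra <- apply(mat[group_a, , drop = FALSE], 2L, fixed_residue)
  rb <- apply(mat[group_b, , drop = FALSE], 2L, fixed_residue)
  cols <- which(!is.na(ra) & !is.na(rb) & ra != rb)
  list(count = length(cols), columns = cols)
}

#' Star alignment of several sequences around the longest
#'
#' Deliberately simple multi-row alignment: every sequence is globally
#' aligned to the longest one (the centre) and the pairwise gap patterns
#' are merged into one common column space. Intended to prepare rows for
#' [conserved_group_differences()]; it is not a progressive MSA and makes
#' no claim of joint optimality.
#'
#' @param records list of nucleotide `seq_record`s (>= 2)
#' @param scoring as in [global_align_nt()]
#' @return named character vector of equal-length gapped rows
#' @export
align_star <- function(records, scoring = default_nt_scoring()) {
  stopifnot(length(records) >= 2L)
  lens <- vapply(records, seq_len_record, 0L)
  centre <- records[[which.max(lens)]]
  others <- records[vapply(records, `[[`, "", "id") != centre$id]
  alns <- lapply(others, function(r) global_align_nt(centre, r, scoring))
  Lc <- seq_len_record(centre)
  # decompose each pairwise alignment into: inserted characters per slot
  # (slot s = between centre residues s and s+1; 0..Lc) and the character
  # aligned to each centre residue ('-' allowed)
  decomp <- lapply(alns, function(aln) {
    rows <- alignment_rows(aln)
    slot <- cumsum(rows$a != "-")
    ins_chars <- lapply(0:Lc, function(s) rows$b[rows$a == "-" & slot == s])
    list(ins = ins_chars, at = rows$b[rows$a != "-"])
  })
  merged_ins <- Reduce(pmax, lapply(decomp, function(d) lengths(d$ins)))
  build_row <- function(ins_chars, at_chars) {
    pieces <- character(2L * Lc + 1L)
    for (s in 0:Lc) {
      chunk <- ins_chars[[s + 1L]]
      pieces[2L * s + 1L] <- paste(c(chunk, rep("-", merged_ins[s + 1L] - length(chunk))),
                                   collapse = "")
      if (s < Lc) pieces[2L * s + 2L] <- at_chars[s + 1L]
    }
    paste(pieces, collapse = "")
  }
  rows_out <- character(length(records))
  names(rows_out) <- vapply(records, `[[`, "", "id")
  rows_out[centre$id] <- build_row(lapply(0:Lc, function(s) character()),
                                   seq_chars(centre))
  for (i in seq_along(alns)) {
    d <- decomp[[i]]
    rows_out[alns[[i]]$b_id] <- build_row(d$ins, d$at)
  }
  rows_out
}

#' Write a window profile as TSV
#'
#' @param profile a `window_profile`
#' @param path output path
#' @export
write_profile_tsv <- function(profile, path) {
  df <- as.data.frame(profile)
  df$identity <- sprintf("%.4f", df$identity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
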