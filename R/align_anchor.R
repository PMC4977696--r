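# Anchored alignment for cluster-length sequences.
#
# Full-matrix affine DP at 54 kb x 54 kb is ~3e9 cells; instead, unique
# shared k-mers (default k = 15) are chained collinearly (longest
# increasing subsequence on their positions), merged into maximal exact
# blocks, and the regions between blocks are aligned by optimal DP. The
# result is exact between anchors; only the anchor placement itself is
# heuristic. Inter-block regions whose DP would still be too large are
# re-anchored with a shorter k and, as a last resort, split at their
# midpoints and aligned piecewise (a documented, bounded heuristic that in
# practice only triggers for long unrelated regions, where no alignment is
# meaningful anyway).

ANCHOR_K <- 15L
ANCHOR_K_FALLBACK <- 11L
# inter-anchor segments up to 8 kb x 8 kb get optimal DP (traceback ~190 MB
# transiently); beyond that, re-anchor then midpoint-split
SEGMENT_MAX_CELLS <- 6.4e7

align_anchored <- function(a, b, S, gap_open, gap_extend, alphabet,
                           k = ANCHOR_K) {
  a_res <- a$residues; b_res <- b$residues
  blocks <- .anchor_blocks(a_res, b_res, k)
  parts <- .assemble_from_blocks(a_res, b_res, blocks, S, gap_open, gap_extend,
                                 alphabet)
  a_gapped <- paste(parts$a, collapse = "")
  b_gapped <- paste(parts$b, collapse = "")
  score <- score_gapped(a_gapped, b_gapped, S, gap_open, gap_extend)
  new_pairwise_alignment(a$id, b$id, a_gapped, b_gapped, score,
                         0L, nchar(a_res), 0L, nchar(b_res), alphabet)
}

# maximal collinear non-overlapping exact blocks:
# data.frame(a_start, b_start, len), 0-based starts
.anchor_blocks <- function(a_res, b_res, k) {
  na <- nchar(a_res); nb <- nchar(b_res)
  empty <- data.frame(a_start = integer(), b_start = integer(), len = integer())
  if (na < k || nb < k) return(empty)
  ka <- substring(a_res, 1:(na - k + 1L), k:na)
  kb <- substring(b_res, 1:(nb - k + 1L), k:nb)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  pos_b <- match(ka, kb)
  keep <- which(ua & !is.na(pos_b) & ub[pmax(pos_b, 1L)])
  if (!length(keep)) return(empty)
  apos <- keep                 # 1-based start in a
  bpos <- pos_b[keep]          # 1-based start in b
  # chain: apos already increasing; LIS (strictly increasing) on bpos
  lis <- .lis_indices(bpos)
  apos <- apos[lis]; bpos <- bpos[lis]
  # merge diagonal runs into blocks
  n <- length(apos)
  brk <- c(TRUE, diff(apos) != diff(bpos) | diff(apos) > k)
  grp <- cumsum(brk)
  a_start <- tapply(apos, grp, function(x) x[1L])
  b_start <- tapply(bpos, grp, function(x) x[1L])
  a_last <- tapply(apos, grp, function(x) x[length(x)])
  blocks <- data.frame(a_start = as.integer(a_start) - 1L,
                       b_start = as.integer(b_start) - 1L,
                       len = as.integer(a_last - a_start) + k)
  # drop stray anchors: chance 15-mer matches between unrelated regions
  # survive the LIS when they are position-compatible, but sit on a
  # diagonal far from both neighbours; forcing the path through them
  # creates large spurious gap blocks. Genuine blocks around a real long
  # indel keep a same-diagonal neighbour on their own side and are safe.
  max_diag_jump <- 1500L
  repeat {
    if (nrow(blocks) < 2L) break
    d <- blocks$a_start - blocks$b_start
    n <- length(d)
    dprev <- c(Inf, abs(diff(d)))
    dnext <- c(abs(diff(d)), Inf)
    stray <- pmin(dprev, dnext) > max_diag_jump & blocks$len < 50L
    if (!any(stray)) break
    blocks <- blocks[!stray, , drop = FALSE]
  }
  # enforce non-overlap between consecutive blocks by trimming fronts
  if (nrow(blocks) > 1L) {
    keep_row <- rep(TRUE, nrow(blocks))
    prev_a <- blocks$a_start[1L] + blocks$len[1L]
    prev_b <- blocks$b_start[1L] + blocks$len[1L]
    for (i in 2:nrow(blocks)) {
      trim <- max(prev_a - blocks$a_start[i], prev_b - blocks$b_start[i], 0L)
      if (blocks$len[i] - trim < 1L) { keep_row[i] <- FALSE; next }
      blocks$a_start[i] <- blocks$a_start[i] + trim
      blocks$b_start[i] <- blocks$b_start[i] + trim
      blocks$len[i] <- blocks$len[i] - trim
      prev_a <- blocks$a_start[i] + blocks$len[i]
      prev_b <- blocks$b_start[i] + blocks$len[i]
    }
    blocks <- blocks[keep_row, , drop = FALSE]
  }
  blocks
}

# indices of one longest strictly-increasing subsequence (patience sorting)
.lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer())
  tails <- integer(n)      # index into x of smallest tail of each length
  parent <- integer(n)
  L <- 0L
  for (i in seq_len(n)) {
    # binary search: first pile whose tail value >= x[i]
    lo <- 1L; hi <- L + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] >= x[i]) hi <- mid else lo <- mid + 1L
    }
    tails[lo] <- i
    parent[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    if (lo > L) L <- lo
  }
  out <- integer(L)
  idx <- tails[L]
  for (j in L:1) { out[j] <- idx; idx <- parent[idx] }
  out
}

.assemble_from_blocks <- function(a_res, b_res, blocks, S, gap_open, gap_extend,
                                  alphabet) {
  alpha <- rownames(S)
  a_parts <- character(); b_parts <- character()
  pa <- 0L; pb <- 0L   # 0-based consumed prefix lengths
  emit_segment <- function(sa, sb) {
    seg <- .align_segment(sa, sb, S, gap_open, gap_extend, alphabet)
    a_parts[[length(a_parts) + 1L]] <<- seg$a
    b_parts[[length(b_parts) + 1L]] <<- seg$b
  }
  if (nrow(blocks)) {
    for (i in seq_len(nrow(blocks))) {
      bs <- blocks[i, ]
      sa <- substr(a_res, pa + 1L, bs$a_start)
      sb <- substr(b_res, pb + 1L, bs$b_start)
      if (nchar(sa) || nchar(sb)) emit_segment(sa, sb)
      blk <- substr(a_res, bs$a_start + 1L, bs$a_start + bs$len)
      a_parts[[length(a_parts) + 1L]] <- blk
      b_parts[[length(b_parts) + 1L]] <- substr(b_res, bs$b_start + 1L,
                                                bs$b_start + bs$len)
      pa <- bs$a_start + bs$len
      pb <- bs$b_start + bs$len
    }
  }
  sa <- substr(a_res, pa + 1L, nchar(a_res))
  sb <- substr(b_res, pb + 1L, nchar(b_res))
  if (nchar(sa) || nchar(sb)) emit_segment(sa, sb)
  list(a = a_parts, b = b_parts)
}

.align_segment <- function(sa, sb, S, gap_open, gap_extend, alphabet,
                           depth = 0L) {
  na <- nchar(sa); nb <- nchar(sb)
  if (na == 0L && nb == 0L) return(list(a = "", b = ""))
  if (na == 0L) return(list(a = strrep("-", nb), b = sb))
  if (nb == 0L) return(list(a = sa, b = strrep("-", na)))
  if (as.double(na) * nb <= SEGMENT_MAX_CELLS) {
    alpha <- rownames(S)
    fit <- .affine_align_cpp(.encode(sa, alpha, "alphabet"),
                             .encode(sb, alpha, "alphabet"),
                             S, gap_open, gap_extend,
                             FALSE, FALSE, FALSE, FALSE)
    ac <- strsplit(sa, "", fixed = TRUE)[[1L]]
    bc <- strsplit(sb, "", fixed = TRUE)[[1L]]
    return(list(a = paste(ifelse(fit$a_idx == 0L, "-", ac[pmax(fit$a_idx, 1L)]),
                          collapse = ""),
                b = paste(ifelse(fit$b_idx == 0L, "-", bc[pmax(fit$b_idx, 1L)]),
                          collapse = "")))
  }
  # too large: re-anchor with a shorter seed, then split as a last resort
  if (depth == 0L) {
    blocks <- .anchor_blocks(sa, sb, ANCHOR_K_FALLBACK)
    if (nrow(blocks)) {
      parts <- .assemble_from_blocks(sa, sb, blocks, S, gap_open, gap_extend,
                                     alphabet)
      return(list(a = paste(parts$a, collapse = ""),
                  b = paste(parts$b, collapse = "")))
    }
  }
  ha <- na %/% 2L; hb <- nb %/% 2L
  left <- .align_segment(substr(sa, 1L, ha), substr(sb, 1L, hb),
                         S, gap_open, gap_extend, alphabet, depth + 1L)
  right <- .align_segment(substr(sa, ha + 1L, na), substr(sb, hb + 1L, nb),
                          S, gap_open, gap_extend, alphabet, depth + 1L)
  list(a = paste0(left$a, right$a), b = paste0(left$b, right$b))
}
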