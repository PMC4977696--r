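# Ortholog mapping between annotated clusters, gene-order collinearity,
# per-protein identity matrices and concatenation-based overall identity.
#
# Orthology is decided by reciprocal best hit under global protein
# identity (exclude_gap_columns policy): clusters hold ~12 genes, so
# all-vs-all global alignment is cheap and fully deterministic.

.translate_cluster <- function(cluster) {
  rec <- cluster$record
  out <- list()
  for (g in cluster$annotation$genes) {
    prot <- tryCatch(suppressWarnings(translate_cds(rec, g)),
                     error = function(e) {
                       warning("gene '", g$gene_id, "' excluded: ",
                               conditionMessage(e))
                       NULL
                     })
    if (!is.null(prot)) out[[g$gene_id]] <- prot
  }
  out
}

#' Map orthologs between two annotated clusters
#'
#' Translates every gene, computes all-vs-all global protein identities
#' and pairs reciprocal best hits with identity >= `min_identity`.
#' Untranslatable genes are excluded with a warning; leftover genes are
#' listed unpaired.
#'
#' @param a,b `annotated_cluster`s
#' @param min_identity minimal protein identity for a pair (default 0.30)
#' @param matrix protein substitution matrix name
#' @return an `ortholog_table`: `pairs` data.frame (`gene_a`, `gene_b`,
#'   `identity`), `unpaired_a`, `unpaired_b`, cluster ids
#' @export
map_orthologs <- function(a, b, min_identity = 0.30, matrix = "BLOSUM62") {
  stopifnot(inherits(a, "annotated_cluster"), inherits(b, "annotated_cluster"))
  pa <- .translate_cluster(a)
  pb <- .translate_cluster(b)
  if (!length(pa) || !length(pb)) stop("no translatable genes")
  ids_a <- names(pa); ids_b <- names(pb)
  M <- matrix(NA_real_, length(pa), length(pb), dimnames = list(ids_a, ids_b))
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    aln <- global_align_aa(pa[[i]], pb[[j]], matrix = matrix)
    M[i, j] <- percent_identity(aln, "exclude_gap_columns")
  }
  best_b <- apply(M, 1L, which.max)   # best hit in b for each a gene
  best_a <- apply(M, 2L, which.max)
  pairs <- data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE)
  for (i in seq_along(ids_a)) {
    j <- best_b[[i]]
    if (best_a[[j]] == i && M[i, j] >= min_identity) {
      pairs <- rbind(pairs, data.frame(gene_a = ids_a[i], gene_b = ids_b[j],
                                       identity = M[i, j],
                                       stringsAsFactors = FALSE))
    }
  }
  structure(list(cluster_a = a$record$id, cluster_b = b$record$id,
                 pairs = pairs,
                 unpaired_a = setdiff(ids_a, pairs$gene_a),
                 unpaired_b = setdiff(ids_b, pairs$gene_b),
                 identity_all = M),
            class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat(sprintf("<ortholog_table> %s vs %s: %d pairs (%d/%d unpaired)\n",
              x$cluster_a, x$cluster_b, nrow(x$pairs),
              length(x$unpaired_a), length(x$unpaired_b)))
  invisible(x)
}

#' Check gene-order collinearity of an ortholog table
#'
#' Orders the ortholog pairs by gene start in cluster A and takes the
#' sequence of B ranks. Orientation is normalized first (deposited
#' clusters may be recorded on either strand): the direction with fewer
#' adjacent rank descents wins, ties going to forward. Breakpoints are the
#' adjacent descents remaining after normalization; the clusters are
#' collinear iff there are none.
#'
#' @param table an `ortholog_table`
#' @param a,b the `cluster_annotation`s (or `annotated_cluster`s) the
#'   table was built from
#' @return a `collinearity_report`: list with `collinear`,
#'   `order_b_given_a`, `breakpoints`, `orientation`
#' @export
check_collinearity <- function(table, a, b) {
  if (inherits(a, "annotated_cluster")) a <- a$annotation
  if (inherits(b, "annotated_cluster")) b <- b$annotation
  pairs <- table$pairs
  if (nrow(pairs) < 2L) stop("insufficient pairs for a collinearity check")
  start_of <- function(annot) {
    s <- vapply(annot$genes, `[[`, 0L, "start")
    names(s) <- vapply(annot$genes, `[[`, "", "gene_id")
    s
  }
  sa <- start_of(a); sb <- start_of(b)
  ord <- order(sa[pairs$gene_a])
  b_rank <- rank(sb[pairs$gene_b])[ord]
  descents <- function(x) sum(diff(x) < 0)
  fwd <- descents(b_rank)
  rev_ <- descents(rev(b_rank))
  orientation <- if (rev_ < fwd) "reverse" else "forward"
  norm <- if (orientation == "reverse") rev(b_rank) else b_rank
  bp <- descents(norm)
  structure(list(collinear = bp == 0L,
                 order_b_given_a = as.integer(b_rank),
                 breakpoints = as.integer(bp),
                 orientation = orientation),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("<collinearity_report> %s (%d breakpoint(s), %s orientation); order: %s\n",
              if (x$collinear) "collinear" else "NOT collinear",
              x$breakpoints, x$orientation,
              paste(x$order_b_given_a, collapse = " ")))
  invisible(x)
}

#' Reference-protein identity matrix across clusters
#'
#' Rows are the reference cluster's proteins (in gene order), columns the
#' other clusters; cells hold the ortholog protein identity in percent, or
#' `NA` when the protein has no ortholog in that cluster ("absent").
#'
#' @param clusters named list of `annotated_cluster`s
#' @param reference_cluster name of the reference cluster in `clusters`
#' @param min_identity,matrix passed to [map_orthologs()]
#' @return numeric matrix (percent identities; `NA` = absent) of class
#'   `identity_matrix`
#' @export
identity_matrix <- function(clusters, reference_cluster, min_identity = 0.30,
                            matrix = "BLOSUM62") {
  if (!reference_cluster %in% names(clusters)) {
    stop("reference cluster '", reference_cluster, "' not in cluster list")
  }
  ref <- clusters[[reference_cluster]]
  others <- setdiff(names(clusters), reference_cluster)
  ref_genes <- vapply(ref$annotation$genes, `[[`, "", "gene_id")
  M <- matrix(NA_real_, length(ref_genes), length(others),
              dimnames = list(ref_genes, others))
  for (cl in others) {
    tab <- map_orthologs(ref, clusters[[cl]], min_identity, matrix)
    M[tab$pairs$gene_a, cl] <- tab$pairs$identity * 100
  }
  structure(M, class = c("identity_matrix", class(M)))
}

#' Overall cluster identity via concatenated protein alignments
#'
#' Restricts to proteins present in \emph{every} cluster (via reciprocal
#' best hits against the first cluster), concatenates the per-protein
#' pairwise alignments for each cluster pair and computes identity over
#' the concatenation (`exclude_gap_columns`). The result equals the
#' non-gap-column-weighted mean of the per-protein identities. Returns a
#' symmetric cluster-by-cluster fraction matrix with unit diagonal.
#'
#' @param clusters named list of >= 2 `annotated_cluster`s
#' @param min_identity,matrix passed to [map_orthologs()]
#' @return symmetric numeric matrix of identity fractions, class
#'   `identity_matrix`, with attribute `proteins` (the universally
#'   present reference proteins used)
#' @export
overall_identity <- function(clusters, min_identity = 0.30, matrix = "BLOSUM62") {
  if (length(clusters) < 2L) stop("need >= 2 clusters")
  if (is.null(names(clusters)) || any(!nzchar(names(clusters)))) {
    stop("clusters must be a named list")
  }
  cl_names <- names(clusters)
  pivot <- clusters[[1L]]
  # gene id of each pivot protein's ortholog in every cluster
  maps <- list()
  maps[[cl_names[1L]]] <- stats::setNames(
    vapply(pivot$annotation$genes, `[[`, "", "gene_id"),
    vapply(pivot$annotation$genes, `[[`, "", "gene_id"))
  for (cl in cl_names[-1L]) {
    tab <- map_orthologs(pivot, clusters[[cl]], min_identity, matrix)
    maps[[cl]] <- stats::setNames(tab$pairs$gene_b, tab$pairs$gene_a)
  }
  universal <- Reduce(intersect, lapply(maps, names))
  if (!length(universal)) stop("no protein occurs in all clusters")
  proteins <- lapply(cl_names, function(cl) {
    trans <- .translate_cluster(clusters[[cl]])
    trans[maps[[cl]][universal]]
  })
  names(proteins) <- cl_names
  n <- length(cl_names)
  M <- diag(1, n)
  dimnames(M) <- list(cl_names, cl_names)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a_gap <- character(length(universal)); b_gap <- character(length(universal))
    for (p in seq_along(universal)) {
      aln <- global_align_aa(proteins[[i]][[p]], proteins[[j]][[p]],
                             matrix = matrix)
      a_gap[p] <- aln$a_gapped; b_gap[p] <- aln$b_gapped
    }
    concat <- new_pairwise_alignment(cl_names[i], cl_names[j],
                                     paste(a_gap, collapse = ""),
                                     paste(b_gap, collapse = ""),
                                     NA_real_, 0L, 0L, 0L, 0L, "protein")
    M[i, j] <- M[j, i] <- percent_identity(concat, "exclude_gap_columns")
  }
  attr(M, "proteins") <- universal
  structure(M, class = c("identity_matrix", class(M)))
}

#' Write an identity matrix as TSV (percent, one decimal)
#'
#' @param m an `identity_matrix`
#' @param path output path
#' @param percent multiply fractions by 100 first (set `FALSE` when the
#'   matrix is already in percent)
#' @export
write_identity_tsv <- function(m, path, percent = TRUE) {
  v <- unclass(m)
  attr(v, "proteins") <- NULL
  if (percent) v <- v * 100
  df <- data.frame(label = rownames(v),
                   apply(v, 2L, function(col) {
                     ifelse(is.na(col), "absent", sprintf("%.1f", col))
                   }),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
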