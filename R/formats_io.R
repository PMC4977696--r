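# FASTA / GFF3 input-output and CDS translation.
#
# Internal coordinates are 0-based half-open everywhere in the package;
# the GFF3 reader/writer is the only place where the 1-based inclusive
# convention of the format is converted.

#' Gene models and cluster annotations
#'
#' A `gene_model` holds one gene: id, 0-based half-open coordinates on its
#' parent sequence, strand and a free-text product. A `cluster_annotation`
#' is the ordered gene set of one sequence (sorted by start, unique ids).
#'
#' @param gene_id unique gene identifier
#' @param start 0-based inclusive start
#' @param end 0-based exclusive end (`start < end`)
#' @param strand `"+"` or `"-"`
#' @param product free-text product description
#' @return a `gene_model`
#' @export
gene_model <- function(gene_id, start, end, strand = "+", product = "") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid coordinates for gene '", gene_id, "': [", start, ", ", end, ")")
  }
  if (!strand %in% c("+", "-")) stop("unknown strand symbol: ", strand)
  structure(list(gene_id = gene_id, start = start, end = end,
                 strand = strand, product = product),
            class = "gene_model")
}

#' @param seq_id id of the annotated sequence
#' @param genes list of `gene_model`s (re-sorted by start)
#' @rdname gene_model
#' @export
cluster_annotation <- function(seq_id, genes = list()) {
  stopifnot(is.character(seq_id), length(seq_id) == 1L)
  if (length(genes)) {
    ids <- vapply(genes, `[[`, "", "gene_id")
    if (anyDuplicated(ids)) {
      stop("duplicate gene ids: ", paste(unique(ids[duplicated(ids)]), collapse = " "))
    }
    genes <- genes[order(vapply(genes, `[[`, 0L, "start"))]
  }
  structure(list(seq_id = seq_id, genes = genes), class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat(sprintf("<cluster_annotation> %s: %d genes\n", x$seq_id, length(x$genes)))
  invisible(x)
}

#' Pair a sequence with its annotation
#'
#' @param record a nucleotide `seq_record`
#' @param annotation a `cluster_annotation` whose genes fit on the record
#' @return an `annotated_cluster`
#' @export
annotated_cluster <- function(record, annotation) {
  stopifnot(inherits(record, "seq_record"), inherits(annotation, "cluster_annotation"))
  n <- seq_len_record(record)
  for (g in annotation$genes) {
    if (g$end > n) stop("gene '", g$gene_id, "' extends past the sequence end")
  }
  structure(list(record = record, annotation = annotation),
            class = "annotated_cluster")
}

#' Read a FASTA file
#'
#' One `seq_record` per header, in file order; residues are uppercased and
#' line breaks removed. IUPAC ambiguity codes are preserved verbatim.
#'
#' @param path path to a FASTA file
#' @param alphabet `"nucleotide"` or `"protein"`
#' @return list of `seq_record`
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- headers[i]
    id <- sub("[[:space:]].*$", "", header)
    desc <- sub("^[^[:space:]]+[[:space:]]*", "", header)
    res <- as.character(set[[i]])
    if (!nzchar(res)) stop("empty sequence for record '", id, "' in ", path)
    out[[i]] <- seq_record(id, res, alphabet = alphabet, description = desc)
  }
  out
}

#' Write records to FASTA
#'
#' Round-trips through [read_fasta()] losslessly for ids and residues.
#'
#' @param records non-empty list of `seq_record` with unique ids
#' @param path output path
#' @param wrap line width (>= 1)
#' @export
write_fasta <- function(records, path, wrap = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  if (!length(records)) stop("no records to write")
  if (wrap < 1L) stop("wrap must be >= 1")
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = " "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    n <- nchar(r$residues)
    starts <- seq.int(1L, n, by = wrap)
    writeLines(substring(r$residues, starts, pmin(starts + wrap - 1L, n)), con)
  }
  invisible(path)
}

#' Read gene/CDS features from a GFF3 file
#'
#' Coordinates are converted from the format's 1-based inclusive convention
#' to the package's 0-based half-open convention. Features are grouped by
#' seqid; when both a `gene` and a `CDS` row carry the same ID, the CDS
#' extent wins (translation must use coding coordinates).
#'
#' @param path path to a GFF3 file
#' @return list of `cluster_annotation`, one per seqid
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  rows <- list()
  for (ln in keep) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) stop("line ", ln, ": expected 9 tab-separated columns")
    type <- f[3L]
    if (!type %in% c("gene", "CDS", "region")) next
    start1 <- suppressWarnings(as.integer(f[4L]))
    end1 <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start1) || is.na(end1)) stop("line ", ln, ": non-numeric coordinates")
    if (end1 < start1) stop("line ", ln, ": end < start")
    strand <- f[7L]
    if (!strand %in% c("+", "-")) stop("line ", ln, ": unknown strand symbol '", strand, "'")
    attrs <- f[9L]
    id <- .gff_attr(attrs, "ID")
    if (is.na(id)) id <- .gff_attr(attrs, "Parent")
    if (is.na(id)) stop("line ", ln, ": feature has neither ID nor Parent attribute")
    product <- .gff_attr(attrs, "product")
    rows[[length(rows) + 1L]] <- list(seqid = f[1L], type = type, id = id,
                                      start = start1 - 1L, end = end1,
                                      strand = strand,
                                      product = if (is.na(product)) "" else product)
  }
  if (!length(rows)) return(list())
  seqids <- unique(vapply(rows, `[[`, "", "seqid"))
  out <- lapply(seqids, function(sq) {
    rs <- Filter(function(r) r$seqid == sq, rows)
    ids <- unique(vapply(rs, `[[`, "", "id"))
    genes <- lapply(ids, function(gid) {
      grs <- Filter(function(r) r$id == gid, rs)
      cds <- Filter(function(r) r$type == "CDS", grs)
      use <- if (length(cds)) cds else grs
      product <- Filter(nzchar, vapply(grs, `[[`, "", "product"))
      gene_model(gid,
                 start = min(vapply(use, `[[`, 0L, "start")),
                 end = max(vapply(use, `[[`, 0L, "end")),
                 strand = use[[1L]]$strand,
                 product = if (length(product)) product[[1L]] else "")
    })
    cluster_annotation(sq, genes)
  })
  names(out) <- seqids
  out
}

.gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))[[1L]]
  if (length(m) < 3L) NA_character_ else m[3L]
}

#' Write a cluster annotation as GFF3
#'
#' Emits 1-based inclusive coordinates; round-trips through [read_gff3()].
#'
#' @param annotation a `cluster_annotation`
#' @param path output path
#' @param type feature type to emit (default `"gene"`)
#' @export
write_gff3 <- function(annotation, path, type = "gene") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in annotation$genes) {
    attrs <- paste0("ID=", g$gene_id)
    if (nzchar(g$product)) attrs <- paste0(attrs, ";product=", g$product)
    writeLines(paste(annotation$seq_id, "bgccompare", type,
                     g$start + 1L, g$end, ".", g$strand, ".", attrs,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Translate an annotated gene
#'
#' Extracts the gene span from the parent record, reverse-complements
#' minus-strand genes, and translates with the standard genetic code. A
#' trailing stop codon is dropped; an internal stop raises a warning and
#' the translation is truncated at the stop.
#'
#' @param record the parent nucleotide `seq_record`
#' @param gene a `gene_model` on that record
#' @return a protein `seq_record` named after the gene
#' @export
translate_cds <- function(record, gene) {
  stopifnot(inherits(record, "seq_record"), inherits(gene, "gene_model"))
  if (record$alphabet != "nucleotide") stop("translation requires a nucleotide record")
  if (gene$end > seq_len_record(record)) {
    stop("gene '", gene$gene_id, "' extends past the sequence end")
  }
  cds <- substr(record$residues, gene$start + 1L, gene$end)
  if (nchar(cds) %% 3L != 0L) {
    stop("gene '", gene$gene_id, "' length ", nchar(cds), " is not divisible by 3")
  }
  if (gene$strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(cds), if.fuzzy.codon = "solve")))
  # drop trailing stop, truncate at internal stop
  aa <- sub("\\*$", "", aa)
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0L) {
    warning("internal stop codon in gene '", gene$gene_id,
            "'; translation truncated at position ", star)
    aa <- substr(aa, 1L, star - 1L)
  }
  if (!nzchar(aa)) stop("gene '", gene$gene_id, "' translates to an empty protein")
  seq_record(gene$gene_id, aa, alphabet = "protein", description = gene$product)
}
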