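#' Sequence records
#'
#' A `seq_record` is the package's lightweight container for one named
#' nucleotide or protein sequence: an id (no whitespace), a free-text
#' description, an uppercase residue string, and an alphabet tag. Gap
#' characters are never stored in a record; gaps exist only inside
#' alignments.
#'
#' @param id sequence identifier (no whitespace)
#' @param residues residue string; uppercased on construction
#' @param alphabet `"nucleotide"` or `"protein"`
#' @param description free text (may be empty)
#' @return an object of class `seq_record`
#' @export
seq_record <- function(id, residues, alphabet = c("nucleotide", "protein"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("id must be a non-empty string")
  }
  if (grepl("[[:space:]]", id)) stop("id contains whitespace: ", id)
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues)) {
    stop("empty sequence for record '", id, "'")
  }
  residues <- toupper(residues)
  chars <- unique(strsplit(residues, "", fixed = TRUE)[[1L]])
  allowed <- if (alphabet == "nucleotide") NT_ALPHABET else c(AA_ALPHABET, "U", "O")
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    stop("record '", id, "' contains non-", alphabet, " characters: ",
         paste(bad, collapse = " "))
  }
  structure(list(id = id, description = description, residues = residues,
                 alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1L, 60L)
  cat(sprintf("<seq_record> %s [%s, %d residues]\n  %s%s\n", x$id, x$alphabet,
              n, head, if (n > 60L) "..." else ""))
  invisible(x)
}

seq_len_record <- function(record) nchar(record$residues)

seq_chars <- function(record) strsplit(record$residues, "", fixed = TRUE)[[1L]]

# substring by 0-based half-open coordinates
seq_slice <- function(record, start, end, id = record$id) {
  stopifnot(start >= 0, end <= seq_len_record(record), start < end)
  seq_record(id, substr(record$residues, start + 1L, end),
             alphabet = record$alphabet, description = record$description)
}

#' Reverse complement of a nucleotide record
#'
#' IUPAC ambiguity codes are complemented correctly (R <-> Y etc.) via
#' Biostrings.
#'
#' @param record a nucleotide `seq_record`
#' @return a `seq_record` with id suffixed `"_rc"`
#' @export
revcomp <- function(record) {
  if (record$alphabet != "nucleotide") stop("revcomp requires a nucleotide record")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(record$residues)))
  seq_record(paste0(record$id, "_rc"), rc, alphabet = "nucleotide",
             description = record$description)
}

# fast IUPAC-aware reverse complement for short strings (avoids DNAString
# construction overhead in inner loops)
revcomp_str <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# evaluate code under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
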