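# Synthetic cluster-evolution generator.
#
# Emulates the comparative scenario of a conserved secondary-metabolite
# gene cluster between close strains: a ~50 kb "core" of ~12 ORFs (one
# NRPS-like megagene of ~21 kb) embedded in unrelated random flanks,
# diverged strain copies at a stated identity, a split into two contigs
# sharing a ~400 bp terminal overlap at ~96 % identity, and planted
# substitution / gap / ambiguity sites. Every stochastic choice is logged
# in a truth object so each pipeline stage can be tested against ground
# truth. Seeds are mandatory function arguments; the caller's RNG state is
# always restored.

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, STOP_CODONS)
})

# ambiguity codes containing each plain base
CODES_FOR_BASE <- local({
  out <- lapply(c("A", "C", "G", "T"), function(base) {
    names(Filter(function(s) base %in% s && length(s) > 1L, IUPAC_SETS))
  })
  names(out) <- c("A", "C", "G", "T")
  out
})

.derive_seed <- function(seed, k) as.integer((as.double(seed) * 1103L + 7919L * k) %% 2147483629)

#' Generate a synthetic cluster genome
#'
#' Builds a random nucleotide "core" of `n_genes` open reading frames
#' (start codon, sense codons, stop codon) on random strands, separated by
#' random intergenic spacers and flanked by unrelated random sequence.
#' One gene is NRPS-like (~21 kb) so the gene-length heterogeneity of real
#' clusters is represented. Defaults yield a core of roughly 50 kb.
#'
#' @param n_genes number of genes (>= 2)
#' @param gene_len_range min/max gene length in bp (rounded to codons)
#' @param nrps_len length of the single NRPS-like gene (bp); `NULL` for none
#' @param intergenic_len_range min/max spacer length in bp
#' @param flank_len unrelated flank length on each side (bp)
#' @param seed RNG seed (mandatory)
#' @return list with `record` (`seq_record`), `annotation`
#'   (`cluster_annotation`), `cluster` (`annotated_cluster`) and `truth`
#' @export
generate_cluster_genome <- function(n_genes = 12L,
                                    gene_len_range = c(900L, 3000L),
                                    nrps_len = 21000L,
                                    intergenic_len_range = c(200L, 1500L),
                                    flank_len = 5000L,
                                    seed) {
  stopifnot(n_genes >= 2L)
  if (gene_len_range[1L] < 9L || gene_len_range[1L] > gene_len_range[2L]) {
    stop("impossible gene length constraints")
  }
  with_seed(seed, {
    lens <- 3L * sample(seq.int(gene_len_range[1L] %/% 3L,
                                gene_len_range[2L] %/% 3L),
                        n_genes, replace = TRUE)
    if (!is.null(nrps_len)) {
      lens[sample.int(n_genes, 1L)] <- 3L * (as.integer(nrps_len) %/% 3L)
    }
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    spacers <- sample(seq.int(intergenic_len_range[1L], intergenic_len_range[2L]),
                      n_genes - 1L, replace = TRUE)
    make_orf <- function(len) {
      ncod <- len %/% 3L - 2L
      paste0("ATG", paste(sample(SENSE_CODONS, ncod, replace = TRUE), collapse = ""),
             sample(STOP_CODONS, 1L))
    }
    parts <- character(); genes <- list()
    pos <- flank_len
    for (i in seq_len(n_genes)) {
      orf <- make_orf(lens[i])
      if (strands[i] == "-") {
        orf <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
      }
      genes[[i]] <- gene_model(sprintf("g%02d", i), pos, pos + lens[i],
                               strand = strands[i],
                               product = if (lens[i] >= 15000L) "NRPS-like synthetase"
                                         else "cluster protein")
      parts <- c(parts, orf)
      pos <- pos + lens[i]
      if (i < n_genes) {
        parts <- c(parts, random_dna(spacers[i]))
        pos <- pos + spacers[i]
      }
    }
    core <- paste(parts, collapse = "")
    residues <- paste0(random_dna(flank_len), core, random_dna(flank_len))
    record <- seq_record(sprintf("synthetic_cluster_s%d", seed), residues,
                         alphabet = "nucleotide",
                         description = "synthetic cluster genome")
    annotation <- cluster_annotation(record$id, genes)
    truth <- list(seed = seed,
                  core_interval = c(start = flank_len, end = flank_len + nchar(core)),
                  core_len = nchar(core),
                  total_len = nchar(residues),
                  n_genes = n_genes)
    list(record = record, annotation = annotation,
         cluster = annotated_cluster(record, annotation), truth = truth)
  })
}

#' Evolve a sequence under substitutions, indels and ambiguity injection
#'
#' Per-site Bernoulli substitutions (uniform over the three alternative
#' bases), Poisson-seeded indels with geometric(+1) lengths, and ambiguity
#' injection (a base is replaced by a compatible IUPAC code). With
#' `protect_orfs`, indel lengths inside annotated genes are rounded up to
#' codon multiples and substitutions avoid creating in-frame stop codons,
#' so evolved genes stay translatable. All events are logged in the truth.
#'
#' @param record nucleotide `seq_record` (plain ACGT sites are mutable)
#' @param sub_rate per-site substitution probability
#' @param indel_rate per-site indel seeding rate
#' @param indel_len_p geometric length parameter (mean length `1/p`)
#' @param ambiguity_rate per-site ambiguity-injection probability
#' @param protect_orfs keep annotated genes frame-intact and stop-free
#' @param annotation `cluster_annotation` (required when `protect_orfs`)
#' @param seed RNG seed (mandatory)
#' @return list with `record` (evolved), `annotation` (coordinates lifted
#'   through the indels; `NULL` if none supplied) and `truth`
#' @export
evolve_sequence <- function(record, sub_rate = 0, indel_rate = 0,
                            indel_len_p = 0.5, ambiguity_rate = 0,
                            protect_orfs = FALSE, annotation = NULL, seed) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1,
            ambiguity_rate >= 0, ambiguity_rate < 1)
  if (sub_rate + indel_rate + ambiguity_rate >= 0.5) {
    stop("combined event rates must stay below 0.5")
  }
  if (protect_orfs && is.null(annotation)) stop("protect_orfs needs an annotation")
  with_seed(seed, {
    chars <- seq_chars(record)
    n <- length(chars)
    plain <- chars %in% c("A", "C", "G", "T")
    sub_pos <- which(stats::runif(n) < sub_rate & plain)
    amb_pos <- setdiff(which(stats::runif(n) < ambiguity_rate & plain), sub_pos)
    n_indel <- stats::rpois(1L, indel_rate * n)
    indel_pos <- if (n_indel > 0L) sort(sample.int(n, min(n_indel, n))) else integer()
    indels <- data.frame(pos = integer(), type = character(), len = integer(),
                         stringsAsFactors = FALSE)
    genes <- if (!is.null(annotation)) annotation$genes else list()
    gene_at <- function(p0) {   # 0-based position -> gene or NULL
      for (g in genes) if (p0 >= g$start && p0 < g$end) return(g)
      NULL
    }
    # substitutions (stop-codon-safe inside genes when protect_orfs)
    subs_to <- character(length(sub_pos))
    for (ii in seq_along(sub_pos)) {
      p <- sub_pos[ii]
      alts <- setdiff(c("A", "C", "G", "T"), chars[p])
      g <- if (protect_orfs) gene_at(p - 1L) else NULL
      if (!is.null(g)) {
        ci <- (p - 1L - g$start) %/% 3L
        cidx <- g$start + 3L * ci + (1:3)            # 1-based codon positions
        ok <- vapply(alts, function(alt) {
          cd <- chars[cidx]; cd[cidx == p] <- alt
          cd <- paste(cd, collapse = "")
          if (g$strand == "-") cd <- revcomp_str(cd)
          !(cd %in% STOP_CODONS)
        }, TRUE)
        alts <- alts[ok]
        if (!length(alts)) { subs_to[ii] <- NA_character_; next }
      }
      choice <- alts[sample.int(length(alts), 1L)]
      subs_to[ii] <- choice
      chars[p] <- choice
    }
    keep <- !is.na(subs_to)
    sub_pos <- sub_pos[keep]; subs_to <- subs_to[keep]
    # ambiguity injection: replace by a compatible code
    amb_to <- character(length(amb_pos))
    for (ii in seq_along(amb_pos)) {
      p <- amb_pos[ii]
      codes <- CODES_FOR_BASE[[chars[p]]]
      amb_to[ii] <- codes[sample.int(length(codes), 1L)]
      chars[p] <- amb_to[ii]
    }
    # indels, applied right-to-left so earlier positions stay valid.
    # With protect_orfs, in-gene events are snapped to codon boundaries and
    # act on whole sense codons (strand-aware), so no chimeric codon — and
    # hence no accidental stop — can arise; deletions never cross a gene
    # boundary.
    if (length(indel_pos)) {
      types <- sample(c("ins", "del"), length(indel_pos), replace = TRUE)
      lens <- stats::rgeom(length(indel_pos), indel_len_p) + 1L
      ins_block <- vector("list", length(indel_pos))
      for (ii in seq_along(indel_pos)) {
        p0 <- indel_pos[ii] - 1L          # 0-based
        L <- lens[ii]
        g <- if (protect_orfs) gene_at(p0) else NULL
        if (protect_orfs && is.null(g) && types[ii] == "del") {
          # intergenic deletion must not reach into a downstream gene
          for (gg in genes) {
            if (p0 < gg$start && p0 + L > gg$start) L <- gg$start - p0
          }
          lens[ii] <- max(1L, L)
        } else if (!is.null(g)) {
          L <- 3L * ((L + 2L) %/% 3L)
          b <- g$start + 3L * ((p0 - g$start) %/% 3L)   # codon start, 0-based
          if (types[ii] == "del") {
            L <- min(L, g$end - b)
            indel_pos[ii] <- b + 1L       # 1-based first deleted base
          } else {
            cod <- sample(SENSE_CODONS, L %/% 3L, replace = TRUE)
            blk <- paste(cod, collapse = "")
            if (g$strand == "-") blk <- revcomp_str(blk)
            ins_block[[ii]] <- strsplit(blk, "", fixed = TRUE)[[1L]]
            indel_pos[ii] <- b            # insert at the codon boundary
          }
          lens[ii] <- L
        }
        if (types[ii] == "ins" && is.null(ins_block[[ii]])) {
          ins_block[[ii]] <- strsplit(random_dna(lens[ii]), "", fixed = TRUE)[[1L]]
        }
      }
      ord <- order(indel_pos)
      indel_pos <- indel_pos[ord]; types <- types[ord]; lens <- lens[ord]
      ins_block <- ins_block[ord]
      indels <- data.frame(pos = indel_pos - ifelse(types == "del", 1L, 0L),
                           type = types, len = lens, stringsAsFactors = FALSE)
      for (ii in rev(seq_along(indel_pos))) {
        p <- indel_pos[ii]
        if (types[ii] == "del") {
          last <- min(p + lens[ii] - 1L, length(chars))
          chars <- chars[-(p:last)]
        } else {
          chars <- append(chars, ins_block[[ii]], after = p)
        }
      }
    }
    evolved <- seq_record(paste0(record$id, "_evolved"), paste(chars, collapse = ""),
                          alphabet = "nucleotide", description = record$description)
    lifted <- if (!is.null(annotation)) .lift_annotation(annotation, indels, nchar(evolved$residues)) else NULL
    truth <- list(seed = seed,
                  substitution_positions = sub_pos - 1L,  # 0-based parent coords
                  substitution_to = subs_to,
                  ambiguity_positions = amb_pos - 1L,
                  ambiguity_to = amb_to,
                  indels = indels,
                  parent_len = n,
                  realized_identity = 1 - length(sub_pos) / n)
    list(record = evolved, annotation = lifted, truth = truth)
  })
}

# shift gene coordinates through logged indel events (0-based event coords)
.lift_annotation <- function(annotation, indels, new_len) {
  shift_at <- function(p0) {
    s <- 0L
    if (nrow(indels)) for (k in seq_len(nrow(indels))) {
      e <- indels[k, ]
      if (e$type == "ins" && e$pos <= p0) s <- s + e$len
      if (e$type == "del" && e$pos < p0) s <- s - min(e$len, p0 - e$pos)
    }
    s
  }
  genes <- lapply(annotation$genes, function(g) {
    ns <- g$start + shift_at(g$start)
    ne <- g$end + shift_at(g$end)
    ns <- max(0L, min(ns, new_len - 1L))
    ne <- max(ns + 1L, min(ne, new_len))
    gene_model(g$gene_id, ns, ne, g$strand, g$product)
  })
  cluster_annotation(annotation$seq_id, genes)
}

#' Split a sequence into two contigs sharing a terminal overlap
#'
#' `left` keeps positions `[0, junction + overlap_len)`; `right` keeps
#' `[junction, end)` with its copy of the shared region independently
#' mutated at `overlap_divergence` (substitutions only). This emulates a
#' cluster sequenced onto two contigs whose assembly broke inside the
#' shared region.
#'
#' @param record nucleotide `seq_record`
#' @param junction 0-based coordinate of the break
#'   (`overlap_len < junction < length - overlap_len`)
#' @param overlap_len shared region length (bp, default 400)
#' @param overlap_divergence per-site substitution rate applied to the
#'   right copy of the shared region (default 0.04)
#' @param seed RNG seed (mandatory)
#' @return list with `left`, `right` (`seq_record`s) and `truth`
#' @export
split_with_overlap <- function(record, junction, overlap_len = 400L,
                               overlap_divergence = 0.04, seed) {
  n <- seq_len_record(record)
  junction <- as.integer(junction); overlap_len <- as.integer(overlap_len)
  if (!(overlap_len < junction && junction < n - overlap_len)) {
    stop("junction must satisfy overlap_len < junction < length - overlap_len")
  }
  with_seed(seed, {
    left <- seq_slice(record, 0L, junction + overlap_len,
                      id = paste0(record$id, "_left"))
    right_chars <- seq_chars(record)[(junction + 1L):n]
    mut <- which(stats::runif(overlap_len) < overlap_divergence &
                   right_chars[seq_len(overlap_len)] %in% c("A", "C", "G", "T"))
    for (p in mut) {
      right_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), right_chars[p]), 1L)
    }
    right <- seq_record(paste0(record$id, "_right"),
                        paste(right_chars, collapse = ""),
                        alphabet = "nucleotide")
    truth <- list(seed = seed, junction = junction, overlap_len = overlap_len,
                  overlap_divergence = overlap_divergence,
                  n_overlap_substitutions = length(mut),
                  realized_overlap_identity = 1 - length(mut) / overlap_len)
    list(left = left, right = right, truth = truth)
  })
}

# plant an exact number of substitutions, gap columns and ambiguities with
# a minimal pairwise separation; used by the reassembly fixture
plant_edits <- function(record, n_sub = 3L, gap_lens = c(12L, 10L, 7L, 5L, 3L, 2L, 1L),
                        n_amb = 12L, min_sep = 100L, margin = 1000L, seed) {
  with_seed(seed, {
    chars <- seq_chars(record)
    n <- length(chars)
    n_events <- n_sub + length(gap_lens) + n_amb
    repeat {
      pos <- sort(sample.int(n - 2L * margin, n_events) + margin)
      if (all(diff(pos) >= min_sep)) break
    }
    roles <- sample(rep(c("sub", "indel", "amb"),
                        c(n_sub, length(gap_lens), n_amb)))
    sub_pos <- pos[roles == "sub"]
    indel_pos <- pos[roles == "indel"]
    amb_pos <- pos[roles == "amb"]
    for (p in sub_pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    for (ii in seq_along(amb_pos)) {
      p <- amb_pos[ii]
      codes <- CODES_FOR_BASE[[chars[p]]]
      chars[p] <- codes[sample.int(length(codes), 1L)]
    }
    types <- sample(c("ins", "del"), length(gap_lens), replace = TRUE)
    lens <- sample(gap_lens)   # shuffle length-to-position assignment
    indels <- data.frame(pos = indel_pos - 1L, type = types, len = lens,
                         stringsAsFactors = FALSE)
    for (ii in rev(seq_along(indel_pos))) {
      p <- indel_pos[ii]
      if (types[ii] == "del") {
        chars <- chars[-(p:(p + lens[ii] - 1L))]
      } else {
        chars <- append(chars, strsplit(random_dna(lens[ii]), "")[[1L]], after = p)
      }
    }
    mutant <- seq_record(paste0(record$id, "_variant"),
                         paste(chars, collapse = ""), alphabet = "nucleotide")
    list(record = mutant,
         truth = list(substitution_positions = sub_pos - 1L,
                      ambiguity_positions = amb_pos - 1L,
                      indels = indels,
                      gap_columns_total = sum(lens)))
  })
}

#' Build a self-contained comparison fixture
#'
#' One fixture per published-style claim:
#' \describe{
#'   \item{ani_vs_ae}{two genomes sharing a ~50 kb core at ~0.89 identity
#'     inside unrelated flanks (windowed-profile / boundary scenario).}
#'   \item{ecd_hty_reassembly}{a reference cluster plus two overlap-split
#'     contigs (400 bp overlap, 4 % divergence) carrying 3 planted genuine
#'     substitutions, 40 planted gap columns and 12 planted compatible
#'     ambiguities relative to the reference.}
#'   \item{marker_panel}{barcode marker pairs differing in 1 bp
#'     (ITS-like), 2 bp (calmodulin-like) and 1 bp + a 3 bp deletion.}
#'   \item{two_clade_msa}{pre-aligned rows from two clades with exactly 30
#'     diagnostic (group-conserved) columns plus single-row noise.}
#' }
#'
#' @param scenario one of the names above
#' @param seed RNG seed (mandatory)
#' @param dir optional output directory; when given, FASTA/GFF3 inputs and
#'   a `truth.json` are written there
#' @return invisible list of in-memory fixture components plus `truth`
#' @export
make_comparison_fixture <- function(scenario, seed, dir = NULL) {
  scenarios <- c("ani_vs_ae", "ecd_hty_reassembly", "marker_panel", "two_clade_msa")
  if (!scenario %in% scenarios) {
    stop("unknown scenario '", scenario, "'; valid: ", paste(scenarios, collapse = ", "))
  }
  fx <- switch(scenario,
               ani_vs_ae = .fixture_ani_vs_ae(seed),
               ecd_hty_reassembly = .fixture_reassembly(seed),
               marker_panel = .fixture_markers(seed),
               two_clade_msa = .fixture_two_clade(seed))
  if (!is.null(dir)) .write_fixture(fx, scenario, dir)
  invisible(fx)
}

.fixture_ani_vs_ae <- function(seed) {
  g <- generate_cluster_genome(seed = .derive_seed(seed, 1L))
  flank_len <- g$truth$core_interval[["start"]]
  core_end <- g$truth$core_interval[["end"]]
  core <- seq_slice(g$record, flank_len, core_end, id = "coreA")
  core_annot <- cluster_annotation("coreA", lapply(g$annotation$genes, function(gm) {
    gene_model(gm$gene_id, gm$start - flank_len, gm$end - flank_len,
               gm$strand, gm$product)
  }))
  ev <- evolve_sequence(core, sub_rate = 0.11, indel_rate = 1e-4,
                        indel_len_p = 0.5, ambiguity_rate = 5e-4,
                        protect_orfs = TRUE, annotation = core_annot,
                        seed = .derive_seed(seed, 2L))
  fB <- with_seed(.derive_seed(seed, 3L),
                  list(l = random_dna(flank_len), r = random_dna(flank_len)))
  recB <- seq_record("genomeB", paste0(fB$l, ev$record$residues, fB$r),
                     alphabet = "nucleotide")
  annotB <- cluster_annotation("genomeB", lapply(ev$annotation$genes, function(gm) {
    gene_model(gm$gene_id, gm$start + flank_len, gm$end + flank_len,
               gm$strand, gm$product)
  }))
  recA <- g$record; recA$id <- "genomeA"
  annotA <- cluster_annotation("genomeA", g$annotation$genes)
  truth <- list(scenario = "ani_vs_ae", seed = seed,
                core_a = unname(g$truth$core_interval),
                core_b = c(flank_len, flank_len + seq_len_record(ev$record)),
                planted_core_identity = 0.89,
                realized_core_identity = ev$truth$realized_identity,
                n_substitutions = length(ev$truth$substitution_positions),
                n_ambiguities = length(ev$truth$ambiguity_positions),
                n_indels = nrow(ev$truth$indels),
                flank_len = flank_len)
  list(genomeA = annotated_cluster(recA, annotA),
       genomeB = annotated_cluster(recB, annotB),
       evolution = ev$truth, truth = truth)
}

.fixture_reassembly <- function(seed) {
  g <- generate_cluster_genome(seed = .derive_seed(seed, 1L))
  ref <- g$record; ref$id <- "reference"
  annot <- cluster_annotation("reference", g$annotation$genes)
  pe <- plant_edits(ref, seed = .derive_seed(seed, 2L))
  mutant <- pe$record; mutant$id <- "strain_variant"
  n <- seq_len_record(mutant)
  junction <- n %/% 2L
  sp <- split_with_overlap(mutant, junction, overlap_len = 400L,
                           overlap_divergence = 0.04,
                           seed = .derive_seed(seed, 3L))
  truth <- list(scenario = "ecd_hty_reassembly", seed = seed,
                substitution_positions = pe$truth$substitution_positions,
                ambiguity_positions = pe$truth$ambiguity_positions,
                indels = pe$truth$indels,
                gap_columns_total = pe$truth$gap_columns_total,
                junction = sp$truth$junction,
                overlap_len = sp$truth$overlap_len,
                realized_overlap_identity = sp$truth$realized_overlap_identity)
  list(reference = ref, annotation = annot, mutant = mutant,
       left = sp$left, right = sp$right, truth = truth)
}

.fixture_markers <- function(seed) {
  with_seed(.derive_seed(seed, 1L), {
    mk <- function(n) random_dna(n)
    its_a <- mk(580L)
    cam_a <- mk(620L)
    del_a <- mk(600L)
    mutate_at <- function(s, pos) {
      ch <- strsplit(s, "")[[1L]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      paste(ch, collapse = "")
    }
    its_pos <- sample.int(560L, 1L) + 10L
    cam_pos <- sort(sample(seq.int(11L, 600L), 2L))
    while (diff(cam_pos) < 20L) cam_pos <- sort(sample(seq.int(11L, 600L), 2L))
    del_sub <- 100L; del_at <- 400L
    its_b <- mutate_at(its_a, its_pos)
    cam_b <- mutate_at(cam_a, cam_pos)
    del_b <- mutate_at(del_a, del_sub)
    del_b <- paste0(substr(del_b, 1L, del_at), substr(del_b, del_at + 4L, 600L))
    records <- list(seq_record("its_strain1", its_a),
                    seq_record("its_strain2", its_b),
                    seq_record("cam_strain1", cam_a),
                    seq_record("cam_strain2", cam_b),
                    seq_record("indel_strain1", del_a),
                    seq_record("indel_strain2", del_b))
    truth <- list(scenario = "marker_panel", seed = seed,
                  its_differences = 1L, cam_differences = 2L,
                  indel_differences = 1L, indel_gap_columns = 3L)
    list(markers = records, truth = truth)
  })
}

.fixture_two_clade <- function(seed, n_per_clade = 4L, len = 600L,
                               n_diagnostic = 30L, noise_rate = 0.01) {
  with_seed(.derive_seed(seed, 1L), {
    anc <- strsplit(random_dna(len), "")[[1L]]
    diag_cols <- sort(sample.int(len, n_diagnostic))
    other_cols <- setdiff(seq_len(len), diag_cols)
    ids_a <- sprintf("cladeA_%d", seq_len(n_per_clade))
    ids_b <- sprintf("cladeB_%d", seq_len(n_per_clade))
    rows <- matrix(rep(anc, 2L * n_per_clade), nrow = 2L * n_per_clade,
                   byrow = TRUE)
    rownames(rows) <- c(ids_a, ids_b)
    # clade B gets a different fixed base at every diagnostic column
    for (cl in diag_cols) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), anc[cl]), 1L)
      rows[ids_b, cl] <- alt
    }
    # single-row noise (substitution, gap or ambiguity) at non-diagnostic
    # columns: one event touches one row only, so it can neither create nor
    # destroy a group-conserved difference
    n_noise <- stats::rbinom(1L, length(other_cols), noise_rate)
    noise_cols <- sample(other_cols, n_noise)
    for (cl in noise_cols) {
      row <- sample.int(2L * n_per_clade, 1L)
      kind <- sample(c("sub", "gap", "amb"), 1L)
      rows[row, cl] <- switch(kind,
                              sub = sample(setdiff(c("A", "C", "G", "T"), rows[row, cl]), 1L),
                              gap = "-",
                              amb = {
                                codes <- CODES_FOR_BASE[[rows[row, cl]]]
                                codes[sample.int(length(codes), 1L)]
                              })
    }
    aligned <- apply(rows, 1L, paste, collapse = "")
    truth <- list(scenario = "two_clade_msa", seed = seed,
                  group_a = ids_a, group_b = ids_b,
                  diagnostic_columns = diag_cols,
                  n_diagnostic = n_diagnostic)
    list(rows = aligned, truth = truth)
  })
}

.write_fixture <- function(fx, scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  if (scenario == "ani_vs_ae") {
    write_fasta(list(fx$genomeA$record), p("genomeA.fasta"))
    write_fasta(list(fx$genomeB$record), p("genomeB.fasta"))
    write_gff3(fx$genomeA$annotation, p("annotA.gff3"))
    write_gff3(fx$genomeB$annotation, p("annotB.gff3"))
  } else if (scenario == "ecd_hty_reassembly") {
    write_fasta(list(fx$reference), p("genomeA.fasta"))
    write_fasta(list(fx$mutant), p("genomeB.fasta"))
    write_gff3(fx$annotation, p("annotA.gff3"))
    dir.create(p("contigs"), showWarnings = FALSE)
    write_fasta(list(fx$left), p("contigs", "left.fasta"))
    write_fasta(list(fx$right), p("contigs", "right.fasta"))
  } else if (scenario == "marker_panel") {
    write_fasta(fx$markers, p("markers.fasta"))
  } else if (scenario == "two_clade_msa") {
    con <- file(p("msa.fasta"), "w")
    for (id in names(fx$rows)) writeLines(c(paste0(">", id), fx$rows[[id]]), con)
    close(con)
  }
  jsonlite::write_json(fx$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
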