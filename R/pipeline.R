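# Pipeline orchestration: configuration handling and the subcommands the
# command-line wrapper (inst/cli/bgccompare.R) exposes. Reports are plain
# TSV/FASTA/GFF3/BED files; floating-point values are written with 4
# decimals for cross-platform byte stability; log messages go to stderr.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated object.
#' Unspecified fields take the package defaults. The configuration
#' round-trips through a flat `key=value` text file via
#' [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param ... named fields overriding the defaults (see Details)
#' @return a `pipeline_config` list
#' @details Fields: `window_size` (50), `identity_policy` ("all_columns"),
#'   `t_high` (0.60), `t_low` (0.40), `max_low_run` (2), `min_len` (100),
#'   `min_identity` (0.90), `max_search` (5000), `match` (2), `mismatch`
#'   (-3), `gap_open` (-18), `gap_extend` (-6), `min_ortholog_identity`
#'   (0.30), `seed` (1), `out_dir` ("."), plus free input fields
#'   (`scenario`, `contigs`, `reference`, `genome_a`, `genome_b`,
#'   `annot_a`, `annot_b`).
#' @export
pipeline_config <- function(...) {
  defaults <- list(window_size = 50L, identity_policy = "all_columns",
                   t_high = 0.60, t_low = 0.40, max_low_run = 2L,
                   min_len = 100L, min_identity = 0.90, max_search = 5000L,
                   match = 2, mismatch = -3, gap_open = -18, gap_extend = -6,
                   min_ortholog_identity = 0.30,
                   seed = 1L, out_dir = ".",
                   scenario = NULL, contigs = NULL, reference = NULL,
                   genome_a = NULL, genome_b = NULL,
                   annot_a = NULL, annot_b = NULL)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = " "))
  cfg <- utils::modifyList(defaults, override)
  stopifnot(cfg$window_size >= 10L,
            cfg$t_low <= cfg$t_high, cfg$t_high <= 1, cfg$t_low >= 0,
            cfg$min_identity >= 0, cfg$min_identity <= 1,
            cfg$min_len >= 1L, cfg$max_low_run >= 0L)
  structure(cfg, class = "pipeline_config")
}

#' @param path path of a flat `key=value` config file
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1L]), "")
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1L], collapse = "="))
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- keys
  ints <- c("window_size", "max_low_run", "min_len", "max_search", "seed")
  for (k in intersect(ints, keys)) vals[[k]] <- as.integer(vals[[k]])
  do.call(pipeline_config, vals)
}

#' @param config a `pipeline_config`
#' @rdname pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  set <- Filter(Negate(is.null), unclass(config))
  writeLines(paste0(names(set), "=", vapply(set, as.character, "")), path)
  invisible(path)
}

.scoring_of <- function(cfg) {
  list(match = cfg$match, mismatch = cfg$mismatch,
       gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
}

.need_input <- function(cfg, fields, command) {
  for (f in fields) {
    v <- cfg[[f]]
    if (is.null(v)) {
      stop(structure(class = c("bgc_missing_input", "error", "condition"),
                     list(message = sprintf("command '%s' needs config field '%s'",
                                            command, f),
                          call = NULL)))
    }
    if (f != "scenario") {
      for (pth in v) if (!file.exists(pth)) {
        stop(structure(class = c("bgc_missing_input", "error", "condition"),
                       list(message = paste0("input not found: ", pth), call = NULL)))
      }
    }
  }
}

.log <- function(...) message("[bgccompare] ", sprintf(...))

#' Run one pipeline stage
#'
#' Dispatches the pipeline subcommands:
#' \describe{
#'   \item{simulate}{write a [make_comparison_fixture()] bundle to `out_dir`.}
#'   \item{profile}{windowed identity profile of two genomes -> `profile.tsv`.}
#'   \item{boundaries}{profile + core delimitation -> `core.gff3` (region
#'     on the first genome) and `boundaries.tsv`.}
#'   \item{merge}{overlap detection, contig merge and (optional) reference
#'     verification -> `merged.fasta`, `merge_report.tsv`,
#'     `provenance.bed`.}
#'   \item{orthologs}{ortholog pairs, collinearity and identity matrices
#'     -> `ortholog_pairs.tsv`, `collinearity.tsv`, `overall_identity.tsv`.}
#'   \item{compare}{profile + boundaries + orthologs for two annotated
#'     genomes.}
#'   \item{report}{collate the TSVs present in `out_dir` into
#'     `summary.tsv`.}
#' }
#' All parameters are logged to stderr; outputs go to `config$out_dir`.
#'
#' @param config a `pipeline_config`
#' @param command one of the subcommands above
#' @return invisibly, a named list of the files written
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "profile", "boundaries",
                                     "merge", "orthologs", "compare", "report")) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .log("command=%s out_dir=%s seed=%d", command, config$out_dir, config$seed)
  switch(command,
         simulate = .cmd_simulate(config),
         profile = .cmd_profile(config, with_boundaries = FALSE),
         boundaries = .cmd_profile(config, with_boundaries = TRUE),
         merge = .cmd_merge(config),
         orthologs = .cmd_orthologs(config),
         compare = .cmd_compare(config),
         report = .cmd_report(config))
}

.cmd_simulate <- function(cfg) {
  .need_input(cfg, "scenario", "simulate")
  make_comparison_fixture(cfg$scenario, cfg$seed, cfg$out_dir)
  .log("scenario=%s written", cfg$scenario)
  invisible(list(dir = cfg$out_dir))
}

.read_one <- function(path) read_fasta(path)[[1L]]

.profile_pair <- function(cfg) {
  a <- .read_one(cfg$genome_a)
  b <- .read_one(cfg$genome_b)
  aln <- global_align_nt(a, b, .scoring_of(cfg))
  list(a = a, b = b, aln = aln,
       profile = window_identity_profile(aln, cfg$window_size))
}

.cmd_profile <- function(cfg, with_boundaries) {
  .need_input(cfg, c("genome_a", "genome_b"), "profile")
  pp <- .profile_pair(cfg)
  files <- list(profile = file.path(cfg$out_dir, "profile.tsv"))
  write_profile_tsv(pp$profile, files$profile)
  .log("profile: %d windows, overall identity %.4f", nrow(pp$profile),
       percent_identity(pp$aln, cfg$identity_policy))
  if (with_boundaries) {
    core <- detect_core_boundaries(pp$profile, cfg$t_high, cfg$t_low,
                                   cfg$max_low_run)
    coords <- alignment_coords(pp$aln)
    ref_start <- coords$a[which(!is.na(coords$a) &
                                  seq_along(coords$a) >= core$col_start)][1L]
    in_core <- !is.na(coords$a) & seq_along(coords$a) <= core$col_end
    ref_end <- max(coords$a[in_core]) + 1L
    core_annot <- cluster_annotation(pp$a$id, list(
      gene_model("core_cluster", ref_start, ref_end, "+",
                 product = "conserved core region")))
    files$core <- file.path(cfg$out_dir, "core.gff3")
    write_gff3(core_annot, files$core, type = "region")
    files$boundaries <- file.path(cfg$out_dir, "boundaries.tsv")
    df <- data.frame(col_start = core$col_start, col_end = core$col_end,
                     ref_start = ref_start, ref_end = ref_end,
                     mean_core_identity = sprintf("%.4f", core$mean_core_identity),
                     mean_flank_identity = sprintf("%.4f", core$mean_flank_identity))
    utils::write.table(df, files$boundaries, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .log("core: columns %d-%d (ref %d-%d)", core$col_start, core$col_end,
         ref_start, ref_end)
  }
  invisible(files)
}

.cmd_merge <- function(cfg) {
  .need_input(cfg, "contigs", "merge")
  contigs <- unlist(lapply(cfg$contigs, read_fasta), recursive = FALSE)
  hit <- find_best_overlap(contigs, cfg$min_len, cfg$min_identity,
                           .scoring_of(cfg), cfg$max_search)
  if (is.null(hit)) {
    stop(structure(class = c("bgc_threshold_error", "error", "condition"),
                   list(message = sprintf(
                     "no overlap passes min_len=%d min_identity=%.2f",
                     cfg$min_len, cfg$min_identity), call = NULL)))
  }
  left <- contigs[[which(vapply(contigs, `[[`, "", "id") == hit$left_id)[1L]]]
  right <- contigs[[which(vapply(contigs, `[[`, "", "id") == hit$right_id)[1L]]]
  merged <- merge_contigs(hit, left, right)
  files <- list(merged = file.path(cfg$out_dir, "merged.fasta"),
                report = file.path(cfg$out_dir, "merge_report.tsv"),
                provenance = file.path(cfg$out_dir, "provenance.bed"))
  write_fasta(list(merged$record), files$merged)
  write_provenance_bed(merged, files$provenance)
  rep <- data.frame(left = hit$left_id, right = hit$right_id,
                    left_orientation = hit$left_orientation,
                    right_orientation = hit$right_orientation,
                    overlap_columns = hit$overlap_columns,
                    overlap_len_left = hit$overlap_len_left,
                    overlap_len_right = hit$overlap_len_right,
                    identity = sprintf("%.4f", hit$identity),
                    junction_start = merged$junction[["start"]],
                    junction_end = merged$junction[["end"]],
                    conflicts = merged$conflicts,
                    reference_identity = NA_character_,
                    inconsistencies = NA_integer_)
  if (!is.null(cfg$reference)) {
    .need_input(cfg, "reference", "merge")
    ref <- .read_one(cfg$reference)
    ver <- reference_verify(merged, ref, cfg$window_size, .scoring_of(cfg))
    rep$reference_identity <- sprintf("%.4f", ver$identity)
    rep$inconsistencies <- ver$inconsistencies
    write_profile_tsv(ver$profile, file.path(cfg$out_dir, "reference_profile.tsv"))
    files$reference_profile <- file.path(cfg$out_dir, "reference_profile.tsv")
    .log("reference identity %.4f, %d genuine inconsistencies",
         ver$identity, ver$inconsistencies)
  }
  utils::write.table(rep, files$report, sep = "\t", quote = FALSE, row.names = FALSE)
  .log("merged %s + %s: %d bp", hit$left_id, hit$right_id,
       seq_len_record(merged$record))
  invisible(files)
}

.load_annotated <- function(fasta, gff) {
  rec <- .read_one(fasta)
  annots <- read_gff3(gff)
  annot <- if (rec$id %in% names(annots)) annots[[rec$id]] else annots[[1L]]
  annot$seq_id <- rec$id
  annotated_cluster(rec, annot)
}

.cmd_orthologs <- function(cfg) {
  .need_input(cfg, c("genome_a", "genome_b", "annot_a", "annot_b"), "orthologs")
  ca <- .load_annotated(cfg$genome_a, cfg$annot_a)
  cb <- .load_annotated(cfg$genome_b, cfg$annot_b)
  tab <- map_orthologs(ca, cb, cfg$min_ortholog_identity)
  files <- list(pairs = file.path(cfg$out_dir, "ortholog_pairs.tsv"),
                collinearity = file.path(cfg$out_dir, "collinearity.tsv"),
                overall = file.path(cfg$out_dir, "overall_identity.tsv"))
  pairs <- tab$pairs
  pairs$identity <- sprintf("%.4f", pairs$identity)
  utils::write.table(pairs, files$pairs, sep = "\t", quote = FALSE, row.names = FALSE)
  col <- check_collinearity(tab, ca, cb)
  utils::write.table(data.frame(collinear = col$collinear,
                                breakpoints = col$breakpoints,
                                orientation = col$orientation,
                                order = paste(col$order_b_given_a, collapse = ",")),
                     files$collinearity, sep = "\t", quote = FALSE, row.names = FALSE)
  clusters <- stats::setNames(list(ca, cb), c(ca$record$id, cb$record$id))
  ov <- overall_identity(clusters, cfg$min_ortholog_identity)
  write_identity_tsv(ov, files$overall)
  .log("%d ortholog pairs; collinear=%s; overall identity %.4f",
       nrow(tab$pairs), col$collinear, ov[1L, 2L])
  invisible(files)
}

.cmd_compare <- function(cfg) {
  out <- .cmd_profile(cfg, with_boundaries = TRUE)
  c(out, .cmd_orthologs(cfg))
}

.cmd_report <- function(cfg) {
  tsvs <- list.files(cfg$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  tsvs <- tsvs[basename(tsvs) != "summary.tsv"]
  rows <- list()
  for (f in tsvs) {
    df <- utils::read.delim(f, check.names = FALSE, colClasses = "character")
    if (!nrow(df)) next
    rows[[length(rows) + 1L]] <- data.frame(
      source = basename(f), key = names(df),
      value = unlist(df[1L, ], use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop(structure(class = c("bgc_missing_input", "error", "condition"),
                   list(message = paste0("no report TSVs in ", cfg$out_dir),
                        call = NULL)))
  }
  out <- file.path(cfg$out_dir, "summary.tsv")
  utils::write.table(do.call(rbind, rows), out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(summary = out))
}
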