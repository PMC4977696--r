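---
title: "Methods: comparing, reassembling and delimiting biosynthetic gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing, reassembling and delimiting biosynthetic gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`bgccompare` answers three questions about secondary-metabolite biosynthetic
gene clusters (BGCs) compared between closely related fungal strains, using
only sequences (FASTA) and gene annotations (GFF3):

* **Delimitation** — where the conserved "core" cluster ends. Between
  related producer strains the cluster region aligns at high nucleotide
  identity while the flanking genomic context is unrelated, so a windowed
  identity profile shows a plateau (often near 90 %) that drops abruptly to
  the baseline identity of unrelated aligned DNA (roughly 30 % per 50 bp
  window, lower once forced gap columns are counted).
* **Reassembly** — whether two deposited "subclusters" on different contigs
  are in fact one cluster split by a misassembly. The operational signal is
  a suffix–prefix overlap of a few hundred bp at high identity; merging
  across it yields a continuous cluster that can be verified against an
  independently deposited full-length sequence.
* **Relatedness** — per-ortholog protein identities, gene-order
  collinearity, and a single overall identity per cluster pair computed on
  the concatenation of per-ortholog protein alignments restricted to
  proteins present in *all* compared clusters.

A central analytic idea throughout is *mismatch triage*: in an alignment of
near-identical sequences, most non-matching columns are one-sided gaps or
IUPAC ambiguity codes whose base sets are compatible with the other row
(`R` vs `A`), and only columns where both rows carry unambiguous, different
bases count as *genuine inconsistencies*. Full-length identity under the
strict policy can read 99.9 % while the genuine-inconsistency identity reads
99.99 %.

# Alignment engine

One affine-gap dynamic program (Rcpp) backs all aligners. A gap of length
$L$ costs $g_o + L \cdot g_e$; defaults are match $+2$, mismatch $-3$,
$g_o=-18$, $g_e=-6$ for nucleotides and BLOSUM62 with $g_o=-11$, $g_e=-1$
for proteins. The nucleotide gap costs are deliberately stiff, and this is
a calibrated choice, not a convention: with cheap gaps (say $-5 - 2L$) the
*optimal* global alignment of unrelated DNA freely interleaves short gaps
to harvest chance matches and reads ~49 % identity per window, erasing the
core/flank contrast; at $-18 - 6L$ unrelated DNA stays near-diagonal and
reads ~35 % — the "about 30 %" baseline that windowed cluster-identity
plots show for flanking regions, and the regime the boundary detector's
thresholds assume. Genuine indels between closely related sequences are
still recovered exactly, because a length difference forces gap columns
regardless of their price (the suite asserts planted gap budgets to the
column). Traceback ties resolve diagonal > up > left, so alignments are
byte-reproducible. Free-end-gap variants implement suffix–prefix overlap
alignment (skipping a prefix of the first and a suffix of the second
sequence is unpenalized); skipped flanks appear only in the span
coordinates, never as gap columns.

Nucleotide scoring treats IUPAC-compatible pairs (intersecting base sets) as
matches. This is a deliberate choice: ambiguity codes are later discounted
in the triage, and scoring them as mismatches would distort gap placement
around exactly the sites the triage needs intact.

**Anchored mode.** Full DP at cluster scale (54 kb × 54 kb ≈ 3×10⁹ cells) is
not desk-scale, so inputs beyond 5 kb × 5 kb are aligned via anchors: k-mers
(k = 15) unique in both sequences are matched, chained collinearly by
longest increasing subsequence, merged into maximal exact blocks, and the
inter-block regions are aligned by optimal DP. The result is optimal
*conditional on the anchor chain*; between anchors it is exact. Oversized
inter-block regions are re-anchored at k = 11 and, as a last resort, split
at their midpoints — a bounded heuristic that in practice only triggers for
long unrelated regions where no alignment is meaningful. The test suite
checks the engine against an independent full-matrix DP oracle on random
pairs (exact score equality), and the anchored path against planted-edit
truths.

# Column classification and identity policies

Each alignment column receives exactly one class, by priority
gap > ambiguity > match > genuine substitution:

* *gap* — `-` in exactly one row (all-gap columns cannot occur);
* *ambiguity* — no gap, at least one IUPAC ambiguity code, base sets
  intersect (`R`|`A`); non-intersecting pairs (`R`|`C`) are genuine
  substitutions;
* *match* — identical unambiguous residues.

Three identity policies are exposed, since published identity figures mix
conventions: `all_columns` (matches / all columns; the package default and
the convention consistent with full-length "99.9 %"-style figures, which
count gaps among non-matching sites), `exclude_gap_columns` (conventional
protein percent identity; used for ortholog tables), and
`exclude_gap_and_ambiguity` (only genuine substitutions count against
identity; the "99.99 %" convention). Note that under `all_columns` a column
where both rows carry the *same* ambiguity code is still classed ambiguity,
not match — identity is claimed only for observed bases.

# Windowed profiles and core delimitation

Profiles tile the alignment with non-overlapping 50-column windows
(alignment-column space, not reference-base space: the published bar plots
run along the alignment, and column space keeps the profile symmetric in
the two sequences). A final partial window is kept if it holds at least half
a window, else merged leftward. Window classes mirror the three published
colour bands: full (identity = 1), partial, low (< 0.30).

Core detection takes the maximal run of windows with identity ≥ `t_high`
(default 0.60 — roughly midway between an ~89 % core and a ~30 % flank),
tolerating interior interruptions of at most `max_low_run` = 2 consecutive
windows that stay ≥ `t_low` = 0.40. Published descriptions say only that
identity "drops abruptly", so sub-window refinement needs a stated rule: the
package reports the first/last column inside the boundary windows where a
50-column running mean of the match indicator crosses
$(t_{high}+t_{low})/2$. Boundary accuracy is asserted at window resolution
(±1 window over 20 seeded replicates).

All thresholds are configuration, not constants; the defaults are the
package's own calibration against its synthetic stated world and are *not*
fitted to any particular dataset.

# Overlap detection and merging

`find_best_overlap` evaluates every ordered contig pair in all four
orientation combinations (deposited subclusters may sit on either strand)
and keeps hits with ≥ 100 bp overlap in both contigs at ≥ 0.90
`all_columns` identity, maximizing identity × min(overlap length). The
default thresholds pass a genuine ~400 bp / 96 % overlap with wide margin
while empirically never passing for unrelated random contigs (the suite
checks a scaled null of shuffled pairs). Only the terminal `max_search`
(default 5 000) bp of each contig enter the DP — a runtime bound, not a
sensitivity parameter, for overlaps shorter than the window.

The merge emits left-unique prefix + overlap consensus + right-unique
suffix. Within the overlap, gap columns contribute the present base;
conflicting residue columns are resolved by `prefer_unambiguous` (take the
unambiguous side when exactly one side is an IUPAC code, else fall back to
the left contig). The junction range is reported in merged (left-frame)
coordinates for GFF3 lift-over, and per-position provenance
(`left`/`consensus`/`right`) is exported as BED.

# Orthologs, collinearity and overall identity

Orthology is reciprocal best hit under global protein identity
(`exclude_gap_columns`), with a 0.30 floor; with ~12 genes per cluster,
all-vs-all global alignment is cheap and deterministic, and no BLAST
dependency is needed. Collinearity orders pairs by gene start in cluster A,
takes B ranks, normalizes orientation (fewer adjacent descents wins; ties
forward) and counts remaining descents as breakpoints; clusters are
collinear iff zero.

Overall identity restricts to proteins present in *every* compared cluster
— per-pair common proteins are deliberately not used, because the two
choices give different values when clusters lack genes — concatenates the
per-protein pairwise alignments, and computes `exclude_gap_columns`
identity, which equals the non-gap-column-weighted mean of per-protein
identities (asserted to 1e−12 in the suite). Whether published per-protein
tables derive from multiple alignments or pairwise alignments is usually
unstated; this package uses pairwise global alignment and treats the
difference as within-tolerance.

# The synthetic stated world

The generator emulates, with logged ground truth:

* a cluster genome: 12 random ORFs (start codon, sense codons, stop) of
  0.9–3 kb plus one ~21 kb NRPS-like megagene, 0.2–1.5 kb intergenic
  spacers, 5 kb unrelated flanks — core ≈ 50 kb, matching the ~51 kb scale
  of real echinocandin-class clusters. (A wider 0.9–6 kb gene range was
  considered but yields ~70 kb cores, inconsistent with the target scale;
  the narrower default keeps the stated 45–60 kb envelope.)
* strain divergence: per-site substitutions (uniform over the three
  alternatives — no transition bias, since identity statistics are
  insensitive to exchange bias), Poisson-seeded indels with geometric
  lengths, ambiguity injection with compatible codes. With `protect_orfs`,
  indels inside genes are codon-multiples and substitutions avoid creating
  in-frame stops, so evolved genes stay translatable. The headline scenario
  plants a 0.89-identity core (substitution rate 0.11, trace indel and
  ambiguity rates).
* a split cluster: contigs `[0, junction+400)` and `[junction, end)` with
  the right copy of the 400 bp shared region diverged at 4 % — the
  ~400 bp / 96 % overlap regime.
* exact-count edit fixtures: 3 substitutions, 40 gap columns (seven indels
  of summed length 40), 12 compatible ambiguities, pairwise separated by
  ≥ 100 bp so that alignment-shift confounding cannot occur.
* a two-clade pre-aligned panel with exactly 30 diagnostic columns; noise
  events touch a single row each, so they can neither create nor destroy a
  group-conserved difference.

What the generator does *not* emulate — realistic GC content and codon
usage, repeat structure, transposons, sequencing error models, phylogenetic
structure along a tree — bounds what a green test establishes: the pipeline
recovers planted truth in i.i.d.-background sequence; it is not evidence
about behaviour on repeat-rich genomes, where unique-k-mer anchoring would
thin out and overlap false positives are conceivable.

# Numerical and degenerate-input choices

* Coordinates: sequence space is 0-based half-open everywhere internally;
  GFF3 emission/ingestion is the only 1-based inclusive boundary. Alignment
  columns are reported 1-based (R indexing convention for positions).
* Tie-breaks: DP traceback diagonal > up > left; equal-scoring overlap hits
  keep the first found (fixed enumeration order); collinearity orientation
  ties go forward.
* Degenerate inputs: empty sequences, single contigs, profiles with no
  window ≥ `t_high` ("no core detected"), < 2 ortholog pairs, and clusters
  without a universally shared protein all raise typed errors rather than
  returning approximations.
* Reports fix floats at 4 decimals for byte-stable outputs; logs go to
  stderr, data to files.

# Known limitations

* Anchored alignment is heuristic where no anchors exist; its identity
  against the optimum is untested for adversarial (repeat-heavy) inputs.
* The overlap search window (`max_search`) bounds detectable overlap length.
* Star alignment around the longest sequence is provided only to prepare
  rows for conserved-difference counting; it is not a progressive MSA.
* Reproducing the printed identity values of deposited clusters requires
  downloading those records; the analysis then depends on the aligner
  parameters of the original (commercial) platform, so agreement is
  expected within tolerance, not bit-exactly.
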