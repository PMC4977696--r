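# bgccompare

Comparative, desk-scale analysis of secondary-metabolite **biosynthetic gene
clusters (BGCs)** between fungal strains. The package is aimed at the common
situation in natural-product genomics where a newly sequenced producer strain
carries a cluster highly similar to one or more deposited clusters, and three
questions have to be answered with nothing but FASTA and GFF3 files:

1. **Where does the cluster end?** Against a related strain, windowed
   nucleotide identity stays high (~90 %) across the conserved "core" cluster
   and drops abruptly to the unrelated-DNA baseline (~30 %) in the flanks.
2. **Is a "split" cluster actually one cluster?** Two deposited subcluster
   contigs that share a terminal overlap (a few hundred bp at high identity)
   can be reassembled into one continuous sequence, then verified against an
   independently deposited full-length cluster. Alignment mismatches are
   triaged into *genuine inconsistencies* (both bases unambiguous and
   different) versus gaps and IUPAC-ambiguity sites.
3. **How related are two clusters?** Reciprocal-best-hit protein orthologs,
   gene-order collinearity, per-protein identity matrices, and one overall
   identity computed over the concatenation of the per-ortholog protein
   alignments restricted to proteins present in every cluster.

## Methods in brief

All aligners share one affine-gap dynamic-programming core (Rcpp):
global (Needleman–Wunsch) and free-end-gap (suffix–prefix overlap) modes,
nucleotide scoring +2/−3 with gap `−18 − 6L` (calibrated so unrelated DNA
reads the ~30 % baseline), protein scoring BLOSUM62 with
gap `−11 − L`. Inputs beyond 5 kb × 5 kb are aligned in *anchored* mode —
unique shared 15-mers, collinear chaining by longest increasing subsequence,
optimal DP between anchors. Windowed identity (50 alignment columns per
window, `all_columns` policy) feeds core delimitation: the maximal window run
at identity ≥ 0.60, tolerating ≤ 2 interior windows ≥ 0.40. Every stage is
validated against a synthetic cluster-evolution generator (~50 kb cores, a
~21 kb NRPS-like megagene, planted divergence, overlaps and edit sites) whose
ground truth is logged per event.

## Worked example

Reassemble a split cluster and verify it against a reference (the numbers
below are what the code prints for seed 5):

```r
library(bgccompare)

fx  <- make_comparison_fixture("ecd_hty_reassembly", seed = 5)
hit <- find_best_overlap(list(fx$left, fx$right), max_search = 1500)
hit
#> <overlap_hit> strain_variant_left(forward) -> strain_variant_right(forward):
#>   400 columns (400/400 bp), identity 0.9725

merged <- merge_contigs(hit, fx$left, fx$right)
ver <- reference_verify(merged, fx$reference)
ver$identity          # 0.9991026  -- "99.9 %"-style full-length identity
ver$inconsistencies   # 3          -- genuinely inconsistent base pairs
```

The two contigs share a 400-column overlap at 97.25 % identity (the fixture
planted 400 bp at 4 % divergence); after merging, the continuous sequence
aligns to the independent reference at 99.9 % identity, and of all
non-matching columns only 3 are genuine base-pair inconsistencies — the rest
are gaps and compatible IUPAC ambiguities, exactly as planted.

Profile and delimit a conserved core:

```r
fx   <- make_comparison_fixture("ani_vs_ae", seed = 11)
aln  <- global_align_nt(fx$genomeA$record, fx$genomeB$record)
prof <- window_identity_profile(aln, 50)
detect_core_boundaries(prof)
#> <core_interval> columns 5051-59800 (windows 102-1196);
#>   core identity 0.889, flank 0.352
```

A command-line wrapper with subcommands `simulate`, `profile`, `boundaries`,
`merge`, `orthologs`, `compare`, `report` is installed at
`system.file("cli", "bgccompare.R", package = "bgccompare")`.

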