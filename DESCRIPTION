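Package: bgccompare
Title: Comparative Delimitation, Reassembly and Relatedness of Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("BGC", "Maintainers", email = "maintainers@bgccompare.org", role = c("aut", "cre"))
Description: Tools for comparing fungal secondary-metabolite biosynthetic gene
    clusters (BGCs) between strains at desk scale. Implements pairwise global
    and free-end-gap nucleotide/protein alignment with an anchored mode for
    cluster-length sequences, sliding-window identity profiling and
    conserved-core boundary delimitation, triage of alignment mismatches into
    genuine inconsistencies versus gaps and IUPAC ambiguities, suffix-prefix
    contig overlap detection and provenance-tracked merging of split
    subclusters, reciprocal-best-hit ortholog mapping with gene-order
    collinearity checks, per-protein and concatenation-based identity
    matrices, and a synthetic cluster-evolution generator that provides
    ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
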