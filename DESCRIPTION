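Package: phyloprune
Title: Tree-Based Orthology Inference, Duplication Mapping, and
    Substitution-Rate Contrasts for Phylotranscriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for phylotranscriptomic dataset construction and
    molecular-evolution analysis from homolog gene trees. Curates putative
    homolog groups (hit filtering, alignment column trimming, iterative
    long-branch cutting, spurious-tip removal, monophyletic/paraphyletic
    isoform masking), decomposes curated homolog trees into ortholog groups
    by rooted-tree paralog pruning, builds partitioned supermatrices with
    occupancy statistics and gene-wise jackknife replicates, locates gene
    and genome duplications on a species tree, computes woody-versus-
    herbaceous substitution-rate contrasts with exact sign tests, and
    builds within-taxon Ks distributions using the Nei-Gojobori (1986)
    method. Includes a gene-family simulator (birth-death duplication and
    loss, episodic whole-genome duplications, habit-linked rate multipliers,
    assembly isoforms, contaminant branches) so every stage is testable
    against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
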