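---
title: "Methods: tree-based orthology, duplication mapping, and rate contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-based orthology, duplication mapping, and rate contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloprune)
```

`phyloprune` implements a homolog-tree-centric phylogenomic workflow:
curation of putative gene families, rooted-tree orthology decomposition,
supermatrix assembly, phylogenetic mapping of gene and genome
duplications, woody-versus-herbaceous substitution-rate contrasts, and
within-taxon Ks distributions. This vignette explains the models and
procedures, the parameters that matter, the numerical conventions, and
what the bundled simulator does and does not establish about real data.

## Data model

Trees are `ape` `phylo` objects; bootstrap supports are carried as
internal-node labels (`node_supports()`), matching the output of common
ML programs; a reader flag accepts the square-bracket comment dialect
instead. Unrooted trees are stored with an arbitrary root; every
operation documented as unrooted-safe (long-branch cutting, rooted-clade
extraction) is tested to give identical tip partitions under random
re-rootings, so no result depends on the stored root's placement.

Sequence ids encode their taxon as the prefix before a configurable
delimiter (default `"@"`). The source data model never states an
id-to-taxon rule, so this convention is ours; it is isolated in
`seq_taxon()`/`taxon_map()` and can be changed in one place. Ambiguity
characters (`X`, `*`, `?`, `.`) count as gaps everywhere occupancy or
character counts are computed.

## Homolog curation

The curation defaults (in `curation_params()`) are the thresholds of the
transcriptome workflow the package targets: hits kept at E ≤ 1e-5,
percent identity strictly > 50 and single-HSP query coverage strictly >
0.7; sequences ≥ 40 aa; clusters with ≥ 8 distinct ingroup taxa; homolog
alignments trimmed at 5% column occupancy (boundary inclusive: a column
exactly at the threshold is kept); ortholog alignments at 30%.

*Identity vs. identical matches.* "Identity" is read as the percent
identity column of the tabular hit format; the identical-residue count
is derived as `round(pident/100 × alignment length)`. Query coverage uses
the single reported HSP — no HSP merging rule is applied because none is
defined for the input format.

*Long-branch cutting* removes every branch longer than the cutoff from
the undirected branch graph and returns each connected component with at
least one tip as a tree. Cutting iterates (2.0, then 0.5 in re-entrant
rounds, then 0.6 on the final tree, in substitutions/site). Because
suppressing a unary node merges branch lengths additively, a component
can transiently contain a merged branch above the cutoff; components are
re-cut until none remains. Components failing the ingroup-taxon filter
are discarded with a logged reason. When no re-alignment/re-inference
hooks are supplied, `curate_pipeline()` reuses the existing alignment and
tree with removed tips dropped ("precomputed mode"); hooks
(`align`, `tree`) plug in external tools per iteration.

*Spurious tips.* A tip is removed when its terminal branch exceeds 0.2
substitutions/site **and** exceeds 10× each of its sisters. A sister that
is a subtree is measured as its stem plus its stepwise-average depth
(below); a `sister = "tip"` mode compares only tip sisters. Both
thresholds must fire — a long branch with a comparably long sister is
biological signal, not artifact.

*Isoform masking.* Within every maximal monophyletic or paraphyletic
same-taxon tip group, only the tip with the most unambiguous characters
in the trimmed alignment survives (ties: lexicographically smallest id).
The implementation iterates two local rules to a fixpoint — merge
same-taxon sister tips; merge a tip with a same-taxon tip that is its
parent's sister — suppressing unary nodes after each removal. In a
connected group the best-covered tip wins every pairwise comparison it
enters, so the fixpoint keeps exactly the per-group maximum. This also
collapses genuine recent paralogs that assemble as same-taxon tip groups;
that loss of recent duplications is inherent to the masking strategy and
is why terminal-branch WGDs are invisible downstream.

## Orthology: rooted-tree (RT) pruning

Clades "rooted by" the designated root taxon are the maximal subtrees
containing no root-taxon tip, each attached by a single branch to a
component that contains one. Extraction re-roots at a root-taxon tip
internally, which makes the result independent of the stored rooting.
The root taxon itself is never inside an ortholog group — with 69 ingroup
and 27 outgroup taxa a full-occupancy group therefore holds 95 taxa,
which the test suite reproduces from the design counts.

At each node whose child subtrees share ≥ 1 taxon, the side with fewer
distinct taxa is pruned (greedily, smallest pair first, at polytomies).
The tie rule is ours (the procedure's source leaves it open): keep the
side with the larger summed unambiguous-character count, then the
lexicographically smallest tip id — maximizing matrix occupancy while
staying deterministic. Pruned sequences are not reconsidered elsewhere.
Every pruning is logged with its duplication node, and the ≤ 1 tip per
taxon postcondition is asserted on every call.

## Supermatrices

Occupancy has two deliberately distinct definitions, stated in all output
headers because the quantities they summarize are often conflated:

* gene occupancy = filled (taxon × gene) cells / (n_taxa × n_genes);
* character occupancy = non-gap characters / (n_taxa × total columns).

Partitions are 1-based inclusive and tile the matrix exactly;
`deconcatenate()` recovers every input alignment byte-identically (a test
asserts this). Jackknife replicates draw `round(fraction × n_genes)`
whole genes without replacement from a seeded RNG; the RNG state of the
caller is saved and restored, so library use never perturbs a session's
randomness. Missing data are written as `"-"`; phylip output is
relaxed-format with padded names, and the partition file uses the
`"WAG, gene = start-end"` convention (model metadata only — fitting is
external).

## Duplication mapping

Only clades that can be trusted are screened: tips all inside the named
taxon set, at least the required number of member taxa present (e.g. 60
of 69 for the focal clade, 3 of 3 for one outgroup set, 18 of 22 for
another), and mean bootstrap ≥ 80% over the clade's internal nodes. The
clade root's label is excluded from that mean — in the label-as-support
convention it annotates the stem branch, which is not part of the clade.
A clade with no internal branch has no support to average and passes
vacuously (only possible when the membership threshold is ≤ 2).

A duplication is a node whose two child subtrees share ≥ 2 taxa
(`min_shared = 2`); requiring two shared taxa suppresses the
single-taxon duplicates that isoform masking makes unreliable, at the
cost of missing terminal-branch WGDs. Each duplication maps to the
species-tree MRCA of all taxa below it; with missing taxa or gene/species
conflict this is the containing, possibly deeper, node. Nested
duplications mapping to one species node count once per extracted clade.

The per-branch proportion needs a denominator that the procedure's
description leaves open. Ours: the number of extracted clades whose taxon
set makes a duplication at that branch *observable* — ≥ 2 taxa from each
child lineage of the branch present. This is flagged in output metadata;
with a different denominator the proportions (not the ranking) change.
Terminal branches have no child lineages and are reported "not
investigated".

## Rate contrasts

For each woody/herbaceous comparison, a candidate sister pair in a clade
is a node with one child whose taxa are a non-empty subset of the woody
set and another inside the herbaceous set; if several nodes qualify, the
one with the most tips is used (earliest node on ties). Branch-model
metadata (`label_branch_model()`) emits the clade with PAML-style `#1` /
`#2` marks and a `model = 2, NSsites = 0, CodonFreq = F3x4` stub; the
codon fit itself is external, and its two output trees (dS, dN) are read
back with branches matched by tip set.

The stepwise average `A(tip) = 0`, `A(v) = mean_c(len(c) + A(c))` weights
cherries, not tips — for `((A:0.1,B:0.1):0.1,C:0.3)` the root value is
0.25, not the tip-path mean 0.233. Each side's length includes its stem
branch by default (`include_stem = FALSE` gives the other reading; the
source procedure is ambiguous) — the stem's substitutions belong to that
lineage's history after the split, so we include them. The signed
contrast (max − min)/min is positive when the herbaceous side is longer;
contrasts outside ±10 are excluded, a zero shorter side is excluded
rather than treated as infinite, and exact ties drop out of the sign
tests (the standard sign-test convention). The two-sided p-value is
2 × the smaller binomial tail capped at 1, which for p = ½ equals the
sum-of-≤-likely-outcomes rule; the suite verifies both equalities against
`binom.test` and exhaustive enumeration for n ≤ 25. Subsampling to
`n_sub` pairs (default 3000) is seeded and recorded; when fewer pairs are
available all are used. The equal-tip-count table repeats everything on
pairs with `woody_tips == herb_tips`, removing the node-density artifact
from the comparison.

## Ks distributions

Hit filtering keeps pairs with pident ≥ 20 and ≥ 50 identical residues,
then removes every sequence with ≥ 10 remaining hits (all its pairs with
it). Whether the hit count is taken before or after thresholding is
unstated in the source procedure; we count after (`count = "pre"`
switches), reasoning that sub-threshold hits are noise that should not
disqualify a sequence. The operation is idempotent.

`ng86()` implements Nei–Gojobori (1986) directly: per-codon synonymous
site fractions (changes to stop codons count as nonsynonymous), site
counts averaged over the two sequences, multi-step codon differences
averaged with equal weight over all orderings of single-nucleotide steps
with stop-codon paths excluded (if every path crosses a stop, all paths
are used), p-distances corrected by d = −(3/4)ln(1 − (4/3)p), and
saturation flagged at pS ≥ 3/4 (Ks reported as NA, never extrapolated).
Codons containing any non-ACGT symbol in either sequence are excluded
from both site and difference counts. The pairwise protein aligner is
pluggable; the built-in is global Needleman–Wunsch with BLOSUM62.
Histograms default to width 0.05 on [0, 2], which resolves the paralog
peak positions of interest (0.3–1, and the deep 1.8–2 signal) without
over-binning; out-of-range and saturated values land in an overflow
bucket.

## The simulator and what passing tests mean

`sim_config()` defines the study conditions. Gene lineages evolve along
a fixed 16-taxon species tree (12 ingroup taxa arranged as three
woody/herbaceous sister comparisons of 3+3, 2+2, and 1+1 taxa; three
outgroups; one deeper root taxon) by lineage-wise Gillespie birth–death.
A WGD applies instantaneously at the start of its branch: each surviving
lineage gains a second retained copy with the retention probability
(default 0.3 on the branch subtending the six-taxon comparison-A clade —
the order of magnitude reported for paleopolyploidy retention). Branch
rates are time × base rate × lognormal noise (sdlog 0.3), ×3 on branches
whose descendant tips are all herbaceous (the upper bound of the
herbaceous/woody rate ratio the contrast analysis targets, applied to
both dS and dN). Base rates (0.3 dS, 0.1 dN substitutions/site per unit
time) are chosen so typical branches sit below the curation cutoffs, as
in real curated data — the deepest outgroup stems occasionally exceed
0.5 under noise and are then honestly cut. Isoforms are near-identical
sister tips (0.005 subs/site) injected per tip with probability 0.05;
contaminants add +3 substitutions/site to one terminal branch per family
with probability 0.02. Synthetic bootstrap supports are drawn uniformly
in [90, 100] so support filters pass unless a test injects low values.
Sequences are only generated where Ks tests need them
(`sim_paralog_pair()` plants the number of synonymous changes that the
NG86 correction maps to the target distance).

What the simulator does **not** emulate: alignment error, model
misspecification in the external codon fits, biased taxon sampling,
hybridization/ILS discordance between gene and species trees (beyond
duplication/loss), and compositional heterogeneity. Passing tests
therefore establish the correctness of the algorithms under the stated
generative model, not the robustness of the biological conclusions to
those real-data complications.

## Numerical conventions and problem sizes

Thresholds are applied with the comparison directions stated above
(strict for hit identity/coverage; inclusive for column occupancy, codon
unambiguity, taxon and length minima, and the Ks hit filters). All
stochastic steps take explicit integer seeds; derived sub-seeds are drawn
below 2³¹. The test suite exercises: 1000 random trees each for the MRCA
oracle and the RT-pruning postcondition; 50 re-rootings per tree for
rooting invariance; exhaustive sign-test enumeration to n = 25; 500
pairs × 300 codons for NG86 recovery (within 15%); 500 replicates of a
44-family null study for the type-I error band [0.035, 0.065] (the
discrete sign test's attainable size at n = 44 is 0.0488); and 20 seeded
500-family simulations for WGD branch recovery (≥ 95% top-ranked).
These sizes were chosen as the smallest that make the corresponding
binomial error bars meaningful.

## Known limitations

* RT pruning discards the smaller duplicate side; duplicate resolution
  strategies that retain both copies (MI/MO) are out of scope.
* No duplication-loss reconciliation model: mapping is MRCA containment,
  so sparse taxon sampling shifts duplications rootward.
* The NG86 estimator saturates near Ks ≈ 2 by construction; deep WGD
  peaks beyond that are outside its range.
* `curate_pipeline()` without hooks reuses the input tree across rounds;
  the full iterate-realign-reinfer loop requires external tools wired in
  through the hooks.
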