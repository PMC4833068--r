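# Woody-vs-herbaceous substitution-rate contrasts: codon alignment
# preparation, branch-model labeling metadata, stepwise averaging, signed
# contrasts with an exclusion window, exact sign tests, and the study
# driver with equal-tip-count node-density control.

#' Contrast definition: a woody/herbaceous sister pair
#'
#' @param label Short label for the comparison (e.g. `"A"`).
#' @param woody Character vector of woody taxa.
#' @param herbaceous Character vector of herbaceous taxa.
#' @param tm Optional [taxon_map()]; when given, habit flags are checked
#'   for consistency.
#' @return An object of class `contrast_definition`.
#' @export
contrast_definition <- function(label, woody, herbaceous, tm = NULL) {
  stopifnot(length(woody) > 0, length(herbaceous) > 0,
            length(intersect(woody, herbaceous)) == 0)
  if (!is.null(tm)) {
    hw <- habit_of(tm, woody); hh <- habit_of(tm, herbaceous)
    if (any(is.na(hw)) || any(hw != "W"))
      stop("woody set contains non-woody taxa under the taxon map")
    if (any(is.na(hh)) || any(hh != "H"))
      stop("herbaceous set contains non-herbaceous taxa under the taxon map")
  }
  structure(list(label = label, woody = woody, herbaceous = herbaceous),
            class = "contrast_definition")
}

#' Read contrast definitions from TSV
#'
#' Columns: `label`, `side` (`W`/`H`), `taxon`.
#' @param file Path to the TSV.
#' @param tm Optional [taxon_map()] for habit checks.
#' @return List of [contrast_definition()]s.
#' @export
read_contrast_definitions <- function(file, tm = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(split(df, df$label), function(d)
    contrast_definition(d$label[1L], d$taxon[d$side == "W"],
                        d$taxon[d$side == "H"], tm))
}

# ---- codon alignment preparation ----------------------------------------

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino acid is replaced by its source codon from the unaligned CDS;
#' alignment gaps become `"---"`. Every codon is cross-checked against the
#' standard genetic code; a terminal stop codon on the CDS is tolerated
#' (and dropped) when the protein lacks it.
#'
#' @param protein_aln Protein alignment (matrix or named strings).
#' @param cds Named character vector id -> CDS nucleotide string.
#' @return Codon alignment matrix (cells are single nucleotides; width =
#'   3 x protein width).
#' @export
back_translate <- function(protein_aln, cds) {
  protein_aln <- as_alignment(protein_aln)
  ids <- rownames(protein_aln)
  miss <- setdiff(ids, names(cds))
  if (length(miss)) stop("CDS missing for: ", paste(miss, collapse = ", "))
  code <- .genetic_code()
  out <- matrix("-", nrow = nrow(protein_aln), ncol = 3L * ncol(protein_aln),
                dimnames = list(ids, NULL))
  for (r in seq_len(nrow(protein_aln))) {
    aa <- protein_aln[r, ]
    res <- aa[!(aa %in% .GAPCHARS)]
    s <- toupper(cds[[ids[r]]])
    if (nchar(s) == 3L * (length(res) + 1L)) {
      last <- substr(s, nchar(s) - 2L, nchar(s))
      if (!is.na(code[last]) && code[last] == "*")
        s <- substr(s, 1L, nchar(s) - 3L)
    }
    if (nchar(s) != 3L * length(res))
      stop(sprintf("CDS length mismatch for %s: %d nt vs %d residues",
                   ids[r], nchar(s), length(res)))
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    trans <- code[codons]
    bad <- which(!is.na(trans) & trans != toupper(res) &
                   toupper(res) != "X")
    if (length(bad))
      stop(sprintf(
        "codon/amino-acid disagreement for %s at residue %d: %s vs %s",
        ids[r], bad[1L], codons[bad[1L]], res[bad[1L]]))
    j <- which(!(aa %in% .GAPCHARS))
    for (k in seq_along(j)) {
      out[r, (3L * (j[k] - 1L) + 1L):(3L * j[k])] <-
        strsplit(codons[k], "")[[1L]]
    }
  }
  out
}

#' Trim codon columns by unambiguous-codon fraction
#'
#' A codon (column triplet) is unambiguous for a row when all three
#' positions are in `{A,C,G,T}`. Codon columns where the fraction of rows
#' with an unambiguous codon is below `min_unambiguous` are removed
#' (boundary inclusive: a fraction equal to the threshold is kept).
#'
#' @param codon_aln Codon alignment (matrix or named strings); width must
#'   be divisible by 3.
#' @param min_unambiguous Minimum fraction of unambiguous codons
#'   (default 0.2).
#' @return Trimmed codon alignment matrix.
#' @export
trim_codon_columns <- function(codon_aln, min_unambiguous = 0.2) {
  aln <- as_alignment(codon_aln)
  if (ncol(aln) %% 3L != 0L) stop("codon alignment width not divisible by 3")
  n_codon <- ncol(aln) %/% 3L
  ok <- toupper(aln) %in% c("A", "C", "G", "T")
  dim(ok) <- dim(aln)
  keep <- logical(n_codon)
  for (k in seq_len(n_codon)) {
    cols <- (3L * (k - 1L) + 1L):(3L * k)
    unamb <- rowSums(ok[, cols, drop = FALSE]) == 3L
    keep[k] <- mean(unamb) >= min_unambiguous
  }
  aln[, rep(keep, each = 3L), drop = FALSE]
}

# ---- rate trees ----------------------------------------------------------

#' Paired per-branch dS and dN trees
#'
#' Container for the output of a branch-model codon analysis: one
#' topology with two sets of branch lengths (synonymous and
#' nonsynonymous substitutions per site).
#'
#' @param topology A rooted `phylo` tree.
#' @param ds,dn Numeric vectors of branch lengths aligned with
#'   `topology$edge` rows; lengths must be non-negative.
#' @return An object of class `rate_trees`.
#' @export
rate_trees <- function(topology, ds, dn) {
  stopifnot(length(ds) == nrow(topology$edge),
            length(dn) == nrow(topology$edge),
            all(ds >= 0), all(dn >= 0))
  structure(list(topology = topology, ds = ds, dn = dn),
            class = "rate_trees")
}

#' Read paired dS/dN newick files sharing one topology
#'
#' Branches of the dN tree are matched to the dS topology by the tip set
#' below each branch.
#'
#' @param ds_file,dn_file Paths to the two newick files.
#' @return A [rate_trees()] object (topology taken from the dS tree).
#' @export
read_rate_trees <- function(ds_file, dn_file) {
  tds <- read_newick(file = ds_file)
  tdn <- read_newick(file = dn_file)
  if (!setequal(tds$tip.label, tdn$tip.label))
    stop("dS and dN trees have different tip sets")
  rate_trees(tds, tds$edge.length, .match_edge_lengths(tds, tdn))
}

#' One sorted-tip-set key per edge (indexed by edge row)
#' @noRd
.edge_keys <- function(tr) {
  desc <- phangorn::Descendants(tr, tr$edge[, 2L], "tips")
  vapply(desc, function(ix)
    paste(sort.int(tr$tip.label[ix]), collapse = "\r"), character(1))
}

#' Transfer branch lengths from `other` onto `topo` by clade tip sets
#' @noRd
.match_edge_lengths <- function(topo, other, topo_keys = .edge_keys(topo)) {
  ix <- match(topo_keys, .edge_keys(other))
  if (anyNA(ix)) stop("dS and dN trees have different topologies")
  other$edge.length[ix]
}

#' Extract root-taxon-rooted clades from a rate-tree object
#'
#' Applies [extract_rooted_clades()] to the topology and carries the dS
#' and dN branch lengths onto each extracted clade (matched by the tip
#' set below each branch).
#'
#' @param rt A [rate_trees()] object.
#' @param tm A [taxon_map()] with a root taxon.
#' @return List of [rate_trees()] objects, one per extracted clade.
#' @export
extract_rate_clades <- function(rt, tm) {
  clades <- extract_rooted_clades(rt$topology, tm)
  if (length(clades) == 0L) return(list())
  full_keys <- .edge_keys(rt$topology)
  lapply(clades, function(cl) {
    ix <- match(.edge_keys(cl), full_keys)
    if (anyNA(ix)) stop("clade edges not found in the source topology")
    rate_trees(cl, rt$ds[ix], rt$dn[ix])
  })
}

# ---- branch-model labeling ----------------------------------------------

#' Identify woody/herbaceous sister pairs and emit branch-model labels
#'
#' Finds every node of the clade whose two child subtrees cleanly separate
#' the definition's woody and herbaceous taxa (one child's taxa a
#' non-empty subset of the woody set, the other's of the herbaceous set).
#' For each candidate, a newick string with PAML-style branch class marks
#' (`#1` on the woody clade, `#2` on the herbaceous clade, background
#' unmarked) and a run-configuration stub (`model = 2`, `NSsites = 0`,
#' `CodonFreq = F3x4`) are emitted for an external branch-model codon
#' analysis.
#'
#' @param clade A rooted `phylo` clade.
#' @param defn A [contrast_definition()].
#' @param tm A [taxon_map()].
#' @return A list of candidates, each a list with `pair_node`,
#'   `woody_child`, `herb_child`, `woody_tips`, `herb_tips`,
#'   `labeled_newick`, `config`. Empty (with a `"reason"` attribute) when
#'   the clade holds no such sister pair.
#' @export
label_branch_model <- function(clade, defn, tm) {
  cands <- .find_pair_nodes(clade, defn, tm)
  if (length(cands) == 0L) {
    out <- list()
    attr(out, "reason") <- "no woody/herbaceous sister pair in clade"
    return(out)
  }
  lapply(cands, function(cd) {
    nw <- .mark_clades(clade, c(cd$woody_child, cd$herb_child),
                       c("#1", "#2"))
    cd$labeled_newick <- nw
    cd$config <- list(model = 2, NSsites = 0, CodonFreq = "F3x4")
    cd
  })
}

#' @noRd
.find_pair_nodes <- function(clade, defn, tm) {
  ntip <- length(clade$tip.label)
  if (ntip < 2L) return(list())
  taxa <- taxon_of(tm, clade$tip.label)
  kids <- .children_list(clade)
  desc <- phangorn::Descendants(clade, seq_len(ntip + clade$Nnode), "tips")
  out <- list()
  for (v in (ntip + 1L):(ntip + clade$Nnode)) {
    ch <- kids[[v]]
    if (length(ch) < 2L) next
    for (i in seq_along(ch)[-length(ch)]) {
      for (j in (i + 1L):length(ch)) {
        for (ord in list(c(i, j), c(j, i))) {
          tw <- unique(taxa[desc[[ch[ord[1L]]]]])
          th <- unique(taxa[desc[[ch[ord[2L]]]]])
          if (length(tw) && length(th) &&
              all(tw %in% defn$woody) && all(th %in% defn$herbaceous)) {
            out[[length(out) + 1L]] <- list(
              pair_node = v,
              woody_child = ch[ord[1L]], herb_child = ch[ord[2L]],
              woody_tips = length(desc[[ch[ord[1L]]]]),
              herb_tips = length(desc[[ch[ord[2L]]]]))
          }
        }
      }
    }
  }
  out
}

#' Append branch-class marks to the newick serialization
#' @noRd
.mark_clades <- function(clade, nodes, marks) {
  tr <- clade
  ntip <- length(tr$tip.label)
  for (k in seq_along(nodes)) {
    v <- nodes[k]
    if (v <= ntip) {
      tr$tip.label[v] <- paste0(tr$tip.label[v], marks[k])
    } else {
      if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
      tr$node.label[v - ntip] <- paste0(tr$node.label[v - ntip], marks[k])
    }
  }
  ape::write.tree(tr)
}

# ---- averaging and contrasts --------------------------------------------

#' Stepwise average branch length from the tips to a node
#'
#' Defined recursively: `A(tip) = 0`;
#' `A(node) = mean over children c of (length(c) + A(c))`. This weights
#' each cherry equally rather than each tip (it is not the arithmetic
#' mean of root-to-tip path lengths).
#'
#' @param tree A rooted `phylo` tree.
#' @param node Node number.
#' @param lengths Optional per-edge lengths aligned with `tree$edge` rows
#'   (defaults to `tree$edge.length`).
#' @return The stepwise average, in the units of the branch lengths.
#' @export
stepwise_average <- function(tree, node, lengths = tree$edge.length) {
  ntip <- length(tree$tip.label)
  kids <- .children_list(tree)
  elen <- function(child) lengths[match(child, tree$edge[, 2L])]
  rec <- function(v) {
    if (v <= ntip) return(0)
    mean(vapply(kids[[v]], function(k) elen(k) + rec(k), numeric(1)))
  }
  rec(node)
}

#' Signed substitution-rate contrast for one sister pair
#'
#' For each metric (dS, dN), each side's average branch length is its stem
#' branch plus the stepwise average of its subtree (`include_stem = FALSE`
#' drops the stem). The contrast is (longer - shorter) / shorter, signed
#' positive when the herbaceous side is longer. Contrasts outside
#' \[-`exclude_abs`, `exclude_abs`\] and pairs with a zero shorter side
#' are flagged excluded.
#'
#' @param rt A [rate_trees()] object for the clade.
#' @param pair_node Node whose two children are the woody and herbaceous
#'   sister clades.
#' @param woody_child,herb_child Child node numbers of `pair_node`.
#' @param label Contrast label carried through to the output.
#' @param exclude_abs Exclusion window half-width (default 10).
#' @param include_stem Include each side's stem branch in its average
#'   (default TRUE).
#' @return An object of class `sister_pair_contrast`: list with `label`,
#'   `ds_contrast`, `dn_contrast`, `woody_tips`, `herb_tips`,
#'   `ds_included`, `dn_included`.
#' @export
compute_contrast <- function(rt, pair_node, woody_child, herb_child,
                             label = NA_character_, exclude_abs = 10,
                             include_stem = TRUE) {
  tr <- rt$topology
  ntip <- length(tr$tip.label)
  one <- function(lengths) {
    stem <- function(v) lengths[match(v, tr$edge[, 2L])]
    lw <- stepwise_average(tr, woody_child, lengths)
    lh <- stepwise_average(tr, herb_child, lengths)
    if (include_stem) {
      lw <- lw + stem(woody_child)
      lh <- lh + stem(herb_child)
    }
    lo <- min(lw, lh); hi <- max(lw, lh)
    if (lo == 0 && hi == 0) return(list(value = 0, included = FALSE))
    if (lo == 0) return(list(value = Inf * sign(lh - lw), included = FALSE))
    v <- (hi - lo) / lo * (if (lh >= lw) 1 else -1)
    list(value = v, included = abs(v) <= exclude_abs)
  }
  ds <- one(rt$ds); dn <- one(rt$dn)
  ndesc <- function(v) length(if (v <= ntip) v else
    phangorn::Descendants(tr, v, "tips")[[1L]])
  structure(list(label = label,
                 ds_contrast = ds$value, dn_contrast = dn$value,
                 woody_tips = ndesc(woody_child),
                 herb_tips = ndesc(herb_child),
                 ds_included = ds$included, dn_included = dn$included),
            class = "sister_pair_contrast")
}

#' Exact two-sided sign test
#'
#' Exact binomial test of `n_pos` positive vs `n_neg` negative signs under
#' a symmetric null (success probability 1/2): p = 2 x the smaller tail,
#' capped at 1. Zeros must be excluded upstream.
#'
#' @param n_pos,n_neg Non-negative counts.
#' @return Two-sided p-value; `NA` (with a warning) when both counts are
#'   zero.
#' @export
sign_test <- function(n_pos, n_neg) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  n <- n_pos + n_neg
  if (n == 0) {
    warning("sign test undefined for zero observations")
    return(NA_real_)
  }
  min(1, 2 * stats::pbinom(min(n_pos, n_neg), n, 0.5))
}

# ---- study driver --------------------------------------------------------

#' Run the full substitution-rate contrast study
#'
#' For each contrast definition: scans every clade for woody/herbaceous
#' sister pairs (when a clade offers several candidate pairs the one with
#' the most tips is used, ties broken by the earliest node), subsamples at
#' most `n_sub` pairs without replacement (seeded), computes signed dS and
#' dN contrasts, and tabulates counts of negative (W > H) and positive
#' (W < H) contrasts, exact sign-test p-values, and median contrasts.
#' Exact ties (zero contrasts) are excluded from the sign tests; contrasts
#' outside the exclusion window are excluded entirely. A second table
#' restricts to pairs where both sides have the same number of tips (the
#' node-density control).
#'
#' @param clades List of [rate_trees()] objects, one per extracted clade.
#' @param defns List of [contrast_definition()]s.
#' @param tm A [taxon_map()].
#' @param n_sub Maximum number of sister pairs per definition
#'   (default 3000); when fewer are available, all are used.
#' @param seed Integer seed for the subsampling.
#' @param exclude_abs Exclusion window half-width (default 10).
#' @param min_ingroup_taxa Minimum distinct ingroup taxa per clade
#'   (default 8).
#' @param include_stem See [compute_contrast()].
#' @return List with `table_all` and `table_equal_tips` (data.frames with
#'   one row per definition x metric: `label`, `metric`, `n_w_gt_h`,
#'   `n_w_lt_h`, `p`, `median_contrast`, `n_pairs`) and `pairs` (the
#'   per-pair contrast data.frame). The seed is recorded in the `"seed"`
#'   attribute.
#' @export
run_contrast_study <- function(clades, defns, tm, n_sub = 3000, seed = 1,
                               exclude_abs = 10, min_ingroup_taxa = 8,
                               include_stem = TRUE) {
  ing <- ingroup_taxa(tm)
  sub_seeds <- .sub_seeds(seed, length(defns))
  pair_rows <- list()
  for (d in seq_along(defns)) {
    defn <- defns[[d]]
    found <- list()
    for (ci in seq_along(clades)) {
      rt <- clades[[ci]]
      taxa <- unique(taxon_of(tm, rt$topology$tip.label))
      if (sum(taxa %in% ing) < min_ingroup_taxa) next
      cands <- .find_pair_nodes(rt$topology, defn, tm)
      if (length(cands) == 0L) next
      sz <- vapply(cands, function(cd) cd$woody_tips + cd$herb_tips,
                   numeric(1))
      cd <- cands[[which.max(sz)]]
      found[[length(found) + 1L]] <- list(clade = ci, cd = cd)
    }
    if (length(found) > n_sub) {
      pick <- .with_seed(sub_seeds[d],
                         sort(sample.int(length(found), n_sub)))
      found <- found[pick]
    }
    for (f in found) {
      ct <- compute_contrast(clades[[f$clade]], f$cd$pair_node,
                             f$cd$woody_child, f$cd$herb_child,
                             label = defn$label, exclude_abs = exclude_abs,
                             include_stem = include_stem)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        label = defn$label, clade = f$clade,
        ds_contrast = ct$ds_contrast, dn_contrast = ct$dn_contrast,
        woody_tips = ct$woody_tips, herb_tips = ct$herb_tips,
        ds_included = ct$ds_included, dn_included = ct$dn_included,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(label = character(), clade = integer(),
               ds_contrast = numeric(), dn_contrast = numeric(),
               woody_tips = integer(), herb_tips = integer(),
               ds_included = logical(), dn_included = logical(),
               stringsAsFactors = FALSE)
  tabulate_one <- function(df) {
    rows <- list()
    for (lab in unique(df$label)) {
      for (metric in c("dS", "dN")) {
        v <- if (metric == "dS") df$ds_contrast[df$label == lab &
                                                  df$ds_included]
             else df$dn_contrast[df$label == lab & df$dn_included]
        n_pos <- sum(v > 0); n_neg <- sum(v < 0)
        rows[[length(rows) + 1L]] <- data.frame(
          label = lab, metric = metric,
          n_w_gt_h = n_neg, n_w_lt_h = n_pos,
          p = if (n_pos + n_neg > 0) sign_test(n_pos, n_neg) else NA_real_,
          median_contrast = if (length(v)) stats::median(v) else NA_real_,
          n_pairs = length(v), stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(label = character(), metric = character(),
                 n_w_gt_h = integer(), n_w_lt_h = integer(), p = numeric(),
                 median_contrast = numeric(), n_pairs = integer(),
                 stringsAsFactors = FALSE)
  }
  out <- list(table_all = tabulate_one(pairs),
              table_equal_tips = tabulate_one(
                pairs[pairs$woody_tips == pairs$herb_tips, , drop = FALSE]),
              pairs = pairs)
  attr(out, "seed") <- seed
  out
}
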