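# Homolog-group curation: hit filtering, column trimming, iterative
# long-branch cutting, spurious-tip removal, isoform masking.

#' Curation parameter set
#'
#' Numeric knobs of the homolog curation stage. Defaults follow the
#' transcriptome-scale workflow this package implements: BLASTP hits kept at
#' E <= 1e-5, percent identity > 50 and query coverage > 0.7; sequences
#' shorter than 40 aa dropped; clusters require >= 8 ingroup taxa; homolog
#' alignments trimmed at 5% column occupancy (30% for ortholog alignments);
#' long branches cut iteratively at 2.0 then 0.5 substitutions/site, with a
#' final-tree cut at 0.6; spurious tips removed when the terminal branch
#' exceeds 0.2 and is more than 10 times its sister.
#'
#' @param evalue_cutoff Maximum E-value for a hit.
#' @param min_ident_pct Minimum percent identity (exclusive).
#' @param min_qcov Minimum query-coverage fraction (exclusive).
#' @param mcl_evalue_cutoff Metadata only: E-value cutoff used by the
#'   external MCL clustering that produced the input clusters.
#' @param min_seq_len_aa Minimum unaligned sequence length (aa), inclusive.
#' @param min_ingroup_taxa Minimum number of distinct ingroup taxa per
#'   cluster, inclusive.
#' @param col_occupancy_homolog Column-occupancy threshold for homolog
#'   alignments.
#' @param col_occupancy_ortholog Column-occupancy threshold for ortholog
#'   alignments.
#' @param branch_cutoffs Ordered, strictly decreasing branch-length cutoffs
#'   (substitutions/site) for the iterative long-branch cutting rounds; the
#'   last value is applied to the final tree.
#' @param spurious_tip_abs Absolute terminal-branch cutoff for spurious-tip
#'   removal.
#' @param spurious_tip_ratio Tip/sister length ratio for spurious-tip
#'   removal.
#' @return An object of class `curation_params`.
#' @export
curation_params <- function(evalue_cutoff = 1e-5,
                            min_ident_pct = 50,
                            min_qcov = 0.7,
                            mcl_evalue_cutoff = 1e-30,
                            min_seq_len_aa = 40,
                            min_ingroup_taxa = 8,
                            col_occupancy_homolog = 0.05,
                            col_occupancy_ortholog = 0.3,
                            branch_cutoffs = c(2.0, 0.5, 0.6),
                            spurious_tip_abs = 0.2,
                            spurious_tip_ratio = 10) {
  p <- list(evalue_cutoff = evalue_cutoff, min_ident_pct = min_ident_pct,
            min_qcov = min_qcov, mcl_evalue_cutoff = mcl_evalue_cutoff,
            min_seq_len_aa = min_seq_len_aa,
            min_ingroup_taxa = min_ingroup_taxa,
            col_occupancy_homolog = col_occupancy_homolog,
            col_occupancy_ortholog = col_occupancy_ortholog,
            branch_cutoffs = branch_cutoffs,
            spurious_tip_abs = spurious_tip_abs,
            spurious_tip_ratio = spurious_tip_ratio)
  stopifnot(all(unlist(p[c(1:3, 5:10)]) >= 0))
  if (length(branch_cutoffs) > 2 &&
      any(diff(branch_cutoffs[1:2]) >= 0))
    stop("iterative branch_cutoffs must be strictly decreasing")
  structure(p, class = "curation_params")
}

#' Homolog group container
#'
#' One putative gene family: unaligned or aligned member sequences plus,
#' when available, the alignment and the gene tree.
#'
#' @param id Group identifier.
#' @param members Named character vector of residue strings (ids as names).
#' @param alignment Optional alignment (matrix or named strings, see
#'   [as_alignment()]).
#' @param tree Optional `phylo` gene tree whose tips are member ids.
#' @return An object of class `homolog_group`.
#' @export
homolog_group <- function(id, members, alignment = NULL, tree = NULL) {
  if (!is.null(alignment)) alignment <- as_alignment(alignment)
  if (!is.null(tree)) {
    extra <- setdiff(tree$tip.label, names(members))
    if (length(extra))
      stop("tree tips not among members: ", paste(extra, collapse = ", "))
  }
  structure(list(id = id, members = members, alignment = alignment,
                 tree = tree),
            class = "homolog_group")
}

#' @export
print.homolog_group <- function(x, ...) {
  cat(sprintf("homolog_group %s: %d sequences%s%s\n", x$id, length(x$members),
              if (is.null(x$alignment)) "" else
                sprintf(", alignment %d cols", ncol(x$alignment)),
              if (is.null(x$tree)) "" else
                sprintf(", tree %d tips", length(x$tree$tip.label))))
  invisible(x)
}

# ---- hit tables ----------------------------------------------------------

#' Read a tabular all-vs-all protein hit report
#'
#' Accepts the standard 12-column tab-separated hit format (query id,
#' subject id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bit score), optionally
#' followed by query length and subject length columns. Query coverage is
#' computed as (qend - qstart + 1) / qlen for the single reported HSP;
#' the identical-residue count as round(pident/100 * alignment length).
#'
#' @param file Path to the tab-separated report.
#' @return A data.frame with columns `query`, `subject`, `pident`,
#'   `length`, `evalue`, `bitscore`, `qlen`, `slen` (NA when absent),
#'   `nident`, `qcov`.
#' @export
read_hit_table <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 12L)
  if (length(bad))
    stop(sprintf("malformed hit row at line %d: %d fields (expected >= 12)",
                 bad[1L], nf[bad[1L]]))
  m <- do.call(rbind, lapply(parts, `[`, 1:14))
  df <- data.frame(
    query = m[, 1L], subject = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    qlen = suppressWarnings(as.integer(m[, 13L])),
    slen = suppressWarnings(as.integer(m[, 14L])),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$pident) | is.na(df$evalue))
  if (length(bad))
    stop("malformed hit row at line ", bad[1L], ": non-numeric field")
  df$nident <- as.integer(round(df$pident / 100 * df$length))
  df$qcov <- (df$qend - df$qstart + 1L) / df$qlen
  df
}

#' Filter all-vs-all hits for homology inference
#'
#' Retains hits with E-value at or below the cutoff, percent identity
#' strictly above `min_ident_pct`, and query-coverage fraction strictly
#' above `min_qcov`; self hits (query == subject) are removed.
#'
#' @param hits Data.frame as from [read_hit_table()] (columns `query`,
#'   `subject`, `pident`, `evalue`, `qcov`).
#' @param params A [curation_params()].
#' @return The retained subset of `hits`.
#' @export
filter_hits <- function(hits, params = curation_params()) {
  keep <- hits$query != hits$subject &
    hits$evalue <= params$evalue_cutoff &
    hits$pident > params$min_ident_pct &
    !is.na(hits$qcov) & hits$qcov > params$min_qcov
  hits[keep, , drop = FALSE]
}

# ---- cluster-level filters ----------------------------------------------

#' Apply length and taxon-count filters to a cluster
#'
#' Drops member sequences shorter than `min_seq_len_aa` (unaligned length,
#' gap characters ignored) and rejects the whole group when fewer than
#' `min_ingroup_taxa` distinct ingroup taxa remain.
#'
#' @param group A [homolog_group()] with unaligned amino-acid members.
#' @param params A [curation_params()].
#' @param tm A [taxon_map()].
#' @return The filtered group, or a [rejected()] sentinel carrying the
#'   rejection reason (test with [is_rejected()]).
#' @export
filter_cluster <- function(group, params = curation_params(), tm) {
  len <- nchar(gsub("-", "", group$members, fixed = TRUE))
  keep <- len >= params$min_seq_len_aa
  members <- group$members[keep]
  taxa <- unique(taxon_of(tm, names(members)))
  n_in <- sum(taxa %in% ingroup_taxa(tm))
  if (n_in < params$min_ingroup_taxa)
    return(rejected(sprintf("ingroup_taxa %d < %d", n_in,
                            params$min_ingroup_taxa)))
  group$members <- members
  if (!is.null(group$alignment))
    group$alignment <- group$alignment[rownames(group$alignment) %in%
                                         names(members), , drop = FALSE]
  if (!is.null(group$tree)) {
    drop <- setdiff(group$tree$tip.label, names(members))
    if (length(drop)) group$tree <- .drop_tips(group$tree, drop)
  }
  group
}

# ---- column trimming -----------------------------------------------------

#' Trim poorly occupied alignment columns
#'
#' Removes columns whose fraction of non-gap, non-ambiguity cells is below
#' `min_occupancy`. Residues are never altered and row order is preserved;
#' rows left with no unambiguous characters are flagged in the
#' `"allgap_rows"` attribute rather than dropped.
#'
#' @param aln Alignment (matrix or named strings).
#' @param min_occupancy Occupancy threshold in (0, 1\]; columns with
#'   occupancy >= the threshold are kept (0 keeps everything).
#' @return Trimmed alignment matrix.
#' @export
trim_columns <- function(aln, min_occupancy) {
  aln <- as_alignment(aln)
  if (ncol(aln) == 0L || nrow(aln) == 0L) stop("empty alignment")
  filled <- !(aln %in% .GAPCHARS)
  dim(filled) <- dim(aln)
  occ <- colMeans(filled)
  out <- aln[, occ >= min_occupancy, drop = FALSE]
  allgap <- rownames(out)[rowSums(!(matrix(out %in% .GAPCHARS,
                                           nrow(out)))) == 0L]
  attr(out, "allgap_rows") <- allgap
  out
}

# ---- long-branch cutting -------------------------------------------------

#' Cut branches longer than a cutoff into connected components
#'
#' Removes every branch whose length exceeds `cutoff` and returns each
#' resulting connected component that contains at least one tip as a tree.
#' The operation is performed on the undirected branch graph, so the
#' partition of tips into components does not depend on the input rooting.
#' Components are re-cut until no returned tree has a branch exceeding the
#' cutoff (branch lengths merged across suppressed unary nodes can exceed
#' it transiently).
#'
#' @param tree A `phylo` tree with branch lengths; may be rooted anywhere.
#' @param cutoff Branch length cutoff in substitutions/site.
#' @return A list of `phylo` trees (single-tip components included).
#' @export
cut_long_branches <- function(tree, cutoff) {
  stopifnot(!is.null(tree$edge.length))
  comps <- .cut_once(tree, cutoff)
  # re-cut components whose merged branches still exceed the cutoff
  out <- list()
  while (length(comps)) {
    tr <- comps[[1L]]
    comps <- comps[-1L]
    if (!is.null(tr$edge.length) && length(tr$edge.length) &&
        max(tr$edge.length) > cutoff && length(tr$tip.label) > 1L) {
      comps <- c(comps, .cut_once(tr, cutoff))
    } else {
      out[[length(out) + 1L]] <- tr
    }
  }
  out
}

#' @noRd
.cut_once <- function(tree, cutoff) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  keep_edge <- tree$edge.length <= cutoff
  # union-find over nodes joined by retained edges
  parent <- seq_len(nnode)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in which(keep_edge)) {
    a <- find(tree$edge[i, 1L]); b <- find(tree$edge[i, 2L])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(nnode), find, integer(1))
  kids <- vector("list", nnode)
  for (i in which(keep_edge)) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  elen <- function(child) tree$edge.length[match(child, tree$edge[, 2L])]
  labs <- if (is.null(tree$node.label)) rep("", tree$Nnode) else tree$node.label
  build <- function(node) {
    # returns list(str=newick fragment, extra=unary-merged length) or NULL
    if (node <= ntip) return(list(str = tree$tip.label[node], extra = 0))
    parts <- list()
    for (k in kids[[node]]) {
      r <- build(k)
      if (!is.null(r)) {
        parts[[length(parts) + 1L]] <-
          paste0(r$str, ":", format(r$extra + elen(k), digits = 12))
        attr(parts[[length(parts)]], "raw") <- r
        attr(parts[[length(parts)]], "len") <- r$extra + elen(k)
      }
    }
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) {
      r <- attr(parts[[1L]], "raw")
      return(list(str = r$str, extra = attr(parts[[1L]], "len")))
    }
    lab <- labs[node - ntip]
    list(str = paste0("(", paste(unlist(parts), collapse = ","), ")", lab),
         extra = 0)
  }
  out <- list()
  for (cc in unique(comp)) {
    nodes <- which(comp == cc)
    if (!any(nodes <= ntip)) next  # component without tips
    # component root: node whose parent edge was cut (or absent)
    par <- .parent_vec(tree)
    roots <- nodes[vapply(nodes, function(n) {
      i <- .edge_to(tree, n)
      is.na(i) || !keep_edge[i]
    }, logical(1))]
    r <- build(roots[1L])
    if (is.null(r)) next
    if (!startsWith(r$str, "(")) {
      # component reduced to a single tip; merged path length becomes its
      # terminal branch
      txt <- paste0("(", r$str, ":", format(r$extra, digits = 12), ");")
    } else {
      txt <- paste0(r$str, ";")
    }
    out[[length(out) + 1L]] <- ape::read.tree(text = txt)
  }
  out
}

# ---- spurious tips -------------------------------------------------------

#' Remove spuriously long terminal branches
#'
#' A tip is removed when its terminal branch exceeds `abs_cutoff` AND is
#' more than `ratio` times the length of each of its sisters. A sister
#' that is itself a tip contributes its terminal branch length; a sister
#' subtree contributes its stem plus the stepwise-average depth of the
#' subtree (see [stepwise_average()]); with `sister = "tip"` only tip
#' sisters are compared and tips with no tip sister are never removed.
#' Unary nodes created by removal are suppressed with branch lengths
#' merged additively.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param abs_cutoff Absolute terminal-branch cutoff (default 0.2).
#' @param ratio Tip/sister ratio (default 10).
#' @param sister How to measure a non-tip sister: `"subtree"` (default,
#'   stepwise-average depth) or `"tip"`.
#' @return The tree with spurious tips removed.
#' @export
remove_spurious_tips <- function(tree, abs_cutoff = 0.2, ratio = 10,
                                 sister = c("subtree", "tip")) {
  sister <- match.arg(sister)
  ntip <- length(tree$tip.label)
  if (ntip < 3L) return(tree)
  kids <- .children_list(tree)
  par <- .parent_vec(tree)
  drop <- character(0)
  for (tip in seq_len(ntip)) {
    t_len <- .stem_length(tree, tip)
    if (t_len <= abs_cutoff) next
    p <- par[tip]
    sibs <- setdiff(kids[[p]], tip)
    if (length(sibs) == 0L) next
    sis_len <- vapply(sibs, function(s) {
      if (s <= ntip) return(.stem_length(tree, s))
      if (sister == "tip") return(NA_real_)
      .stem_length(tree, s) + stepwise_average(tree, s)
    }, numeric(1))
    sis_len <- sis_len[!is.na(sis_len)]
    if (length(sis_len) == 0L) next
    if (all(t_len > ratio * sis_len)) drop <- c(drop, tree$tip.label[tip])
  }
  if (length(drop) == 0L || length(drop) >= ntip - 1L) return(tree)
  .drop_tips(tree, drop)
}

#' drop.tip that tolerates shrinking to a single tip
#' @noRd
.drop_tips <- function(tree, labels) {
  keep <- setdiff(tree$tip.label, labels)
  if (length(keep) == 0L) return(NULL)
  if (length(keep) == 1L) {
    node <- match(keep, tree$tip.label)
    return(structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          tip.label = keep,
                          edge.length = .stem_length(tree, node),
                          Nnode = 1L), class = "phylo"))
  }
  ape::drop.tip(tree, labels)
}

# ---- isoform masking -----------------------------------------------------

#' Mask redundant isoform tips of the same taxon
#'
#' Transcriptome assembly yields multiple isoforms of one gene that appear
#' as monophyletic or paraphyletic tip groups of a single taxon. Within
#' every such maximal group exactly one tip is kept: the one with the most
#' unambiguous characters in the trimmed alignment (ties broken by the
#' lexicographically smallest id). The procedure iterates two local rules
#' to a fixpoint: same-taxon tips that are sisters are merged, and a tip
#' whose parent's sister is a same-taxon tip is merged with it (the
#' paraphyletic grade case); each merge keeps the better-covered tip and
#' suppresses the resulting unary node.
#'
#' @param tree A `phylo` gene tree.
#' @param tm A [taxon_map()] (supplies the id-to-taxon rule).
#' @param char_counts Named integer vector id -> unambiguous character
#'   count, as from [count_unambiguous()].
#' @return The masked tree.
#' @export
mask_isoform_tips <- function(tree, tm, char_counts) {
  miss <- setdiff(tree$tip.label, names(char_counts))
  if (length(miss))
    stop("missing character count for tip(s): ", paste(miss, collapse = ", "))
  better <- function(a, b) {
    # keep a over b?
    ca <- char_counts[[a]]; cb <- char_counts[[b]]
    ca > cb || (ca == cb && a < b)
  }
  repeat {
    ntip <- length(tree$tip.label)
    if (ntip <= 1L) break
    kids <- .children_list(tree)
    par <- .parent_vec(tree)
    taxa <- taxon_of(tm, tree$tip.label)
    drop <- NULL
    # monophyletic: same-taxon tip children of one node
    for (p in (ntip + 1L):(ntip + tree$Nnode)) {
      tipkids <- kids[[p]][kids[[p]] <= ntip]
      if (length(tipkids) < 2L) next
      tx <- taxa[tipkids]
      for (t in unique(tx[duplicated(tx)])) {
        ids <- tree$tip.label[tipkids[tx == t]]
        best <- ids[1L]
        for (id in ids[-1L]) if (better(id, best)) best <- id
        drop <- c(drop, setdiff(ids, best))
      }
      if (!is.null(drop)) break
    }
    # paraphyletic: tip vs tip sister of its parent
    if (is.null(drop)) {
      for (tip in seq_len(ntip)) {
        p <- par[tip]
        if (is.na(p)) next
        g <- par[p]
        if (is.na(g)) next
        uncles <- setdiff(kids[[g]], p)
        tipuncles <- uncles[uncles <= ntip]
        same <- tipuncles[taxa[tipuncles] == taxa[tip]]
        if (length(same)) {
          a <- tree$tip.label[tip]; b <- tree$tip.label[same[1L]]
          drop <- if (better(a, b)) b else a
          break
        }
      }
    }
    if (is.null(drop)) break
    tree <- .drop_tips(tree, drop)
    if (is.null(tree) || length(tree$tip.label) <= 1L) break
  }
  tree
}

# ---- full curation pipeline ----------------------------------------------

#' Run the homolog curation pipeline on one cluster
#'
#' Applies, in order: cluster filters ([filter_cluster()]); column trimming
#' of the alignment; iterative long-branch cutting at each of the first
#' `length(branch_cutoffs) - 1` cutoffs, re-applying cluster filters to
#' every component and (when hooks are provided) re-aligning and
#' re-estimating the tree of each component; then, on the final tree of
#' each surviving component, a cut at the last cutoff, spurious-tip
#' removal, and isoform masking. Alignment and tree estimation are
#' delegated to pluggable hooks; in their absence the existing alignment
#' and tree are reused with removed tips dropped (precomputed mode).
#'
#' @param group A [homolog_group()] with members, and with an alignment and
#'   tree unless hooks supply them.
#' @param params A [curation_params()].
#' @param tm A [taxon_map()].
#' @param hooks Optional list with functions `align(members) -> alignment`
#'   and `tree(alignment) -> phylo`. A hook failure aborts with the stage
#'   name.
#' @return A list of curated [homolog_group()]s; every removal is recorded
#'   in the `"removal_log"` attribute (data.frame with columns `stage`,
#'   `id`, `reason`).
#' @export
curate_pipeline <- function(group, params = curation_params(), tm,
                            hooks = NULL) {
  log <- data.frame(stage = character(), id = character(),
                    reason = character(), stringsAsFactors = FALSE)
  note <- function(stage, ids, reason) {
    if (length(ids))
      log <<- rbind(log, data.frame(stage = stage, id = ids, reason = reason,
                                    stringsAsFactors = FALSE))
  }
  run_hook <- function(name, f, ...) {
    out <- tryCatch(f(...), error = function(e)
      stop(sprintf("hook failure at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
    out
  }
  prepare <- function(g) {
    # ensure alignment + tree consistent with current members
    if (!is.null(hooks$align)) {
      g$alignment <- as_alignment(run_hook("align", hooks$align, g$members))
    } else if (is.null(g$alignment)) {
      stop("no alignment and no align hook supplied")
    }
    g$alignment <- trim_columns(g$alignment, params$col_occupancy_homolog)
    if (!is.null(hooks$tree)) {
      g$tree <- run_hook("tree", hooks$tree, g$alignment)
    } else if (is.null(g$tree)) {
      stop("no tree and no tree hook supplied")
    }
    g
  }
  before <- names(group$members)
  g0 <- filter_cluster(group, params, tm)
  if (is_rejected(g0)) {
    note("cluster_filter", group$id, g0$reason)
    out <- list()
    attr(out, "removal_log") <- log
    return(out)
  }
  note("length_filter", setdiff(before, names(g0$members)), "short_sequence")
  g0 <- prepare(g0)

  cutoffs <- params$branch_cutoffs
  iter_cutoffs <- head(cutoffs, -1L)
  final_cutoff <- cutoffs[length(cutoffs)]

  groups <- list(g0)
  for (co in iter_cutoffs) {
    nxt <- list()
    for (g in groups) {
      comps <- cut_long_branches(g$tree, co)
      if (length(comps) > 1L)
        note("branch_cut", g$id, sprintf("split_at_%g", co))
      serial <- 0L
      for (tr in comps) {
        serial <- serial + 1L
        gid <- if (length(comps) == 1L) g$id else
          paste0(g$id, "_", co, "_", serial)
        sub <- homolog_group(gid, g$members[tr$tip.label])
        sub$alignment <- g$alignment[rownames(g$alignment) %in%
                                       tr$tip.label, , drop = FALSE]
        sub$tree <- tr
        fs <- filter_cluster(sub, params, tm)
        if (is_rejected(fs)) {
          note("component_filter", gid, fs$reason)
          next
        }
        fs <- prepare(fs)
        nxt[[length(nxt) + 1L]] <- fs
      }
    }
    groups <- nxt
  }

  out <- list()
  for (g in groups) {
    comps <- cut_long_branches(g$tree, final_cutoff)
    serial <- 0L
    for (tr in comps) {
      serial <- serial + 1L
      gid <- if (length(comps) == 1L) g$id else paste0(g$id, "_f", serial)
      before_tips <- tr$tip.label
      tr <- remove_spurious_tips(tr, params$spurious_tip_abs,
                                 params$spurious_tip_ratio)
      note("spurious_tip", setdiff(before_tips, tr$tip.label), "long_terminal")
      aln <- g$alignment[rownames(g$alignment) %in% tr$tip.label, ,
                         drop = FALSE]
      cc <- count_unambiguous(aln)
      before_tips <- tr$tip.label
      tr <- mask_isoform_tips(tr, tm, cc)
      note("isoform_mask", setdiff(before_tips, tr$tip.label),
           "redundant_isoform")
      sub <- homolog_group(gid, g$members[tr$tip.label])
      sub$alignment <- g$alignment[rownames(g$alignment) %in%
                                     tr$tip.label, , drop = FALSE]
      sub$tree <- tr
      fs <- filter_cluster(sub, params, tm)
      if (is_rejected(fs)) {
        note("final_filter", gid, fs$reason)
        next
      }
      out[[length(out) + 1L]] <- fs
    }
  }
  attr(out, "removal_log") <- log
  out
}
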