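# Orthology inference by rooted-tree (RT) paralog pruning: extract clades
# rooted by the designated outgroup taxon, then prune the smaller side of
# every node whose child subtrees share taxa.

#' Extract clades rooted by the designated root taxon
#'
#' From an (effectively unrooted) homolog tree containing one or more tips
#' of the root taxon, returns every maximal subtree that contains no
#' root-taxon tip and is separated from a root-taxon tip by a single
#' branch. Each returned clade is rooted at that branch. The result does
#' not depend on how the input tree happens to be rooted.
#'
#' @param tree A `phylo` homolog tree.
#' @param tm A [taxon_map()] with a non-NULL `root_taxon`.
#' @return A list of rooted `phylo` clades; empty when the tree has no
#'   root-taxon tip (logged via a message, not an error).
#' @export
extract_rooted_clades <- function(tree, tm) {
  if (is.null(tm$root_taxon)) stop("taxon map has no root_taxon")
  taxa <- taxon_of(tm, tree$tip.label)
  root_tips <- tree$tip.label[taxa == tm$root_taxon]
  if (length(root_tips) == 0L) {
    message("no root-taxon tip; no clades extracted")
    return(list())
  }
  if (length(tree$tip.label) - length(root_tips) < 1L) return(list())
  # root at a root-taxon tip so that "contains no root-taxon tip" clades
  # are exactly the maximal such rooted subtrees; the choice of which
  # root-taxon tip is immaterial for the extracted tip sets
  tr <- .reroot_at_tip(tree, root_tips[1L])
  ntip <- length(tr$tip.label)
  taxa <- taxon_of(tm, tr$tip.label)
  is_root_tip <- taxa == tm$root_taxon
  # per-node count of root-taxon tips below
  desc <- phangorn::Descendants(tr, seq_len(ntip + tr$Nnode), "tips")
  n_root_below <- vapply(desc, function(ix) sum(is_root_tip[ix]), integer(1))
  par <- .parent_vec(tr)
  out <- list()
  for (v in seq_len(ntip + tr$Nnode)) {
    if (n_root_below[v] > 0L) next
    p <- par[v]
    if (is.na(p)) next
    if (n_root_below[p] > 0L) {
      cl <- extract_subtree(tr, v)
      if (length(cl$tip.label) >= 1L) out[[length(out) + 1L]] <- cl
    }
  }
  out
}

#' Prune paralogous subtrees from a rooted clade (RT pruning)
#'
#' Traverses the clade from the root toward the tips. At every node whose
#' child subtrees share one or more taxa, a gene duplication is inferred
#' and the child subtree with the smaller number of distinct taxa is
#' pruned; at a polytomy child pairs are evaluated and pruned greedily
#' (smallest side first) until the children are pairwise disjoint. Ties in
#' taxon count are broken by keeping the side with the greater summed
#' unambiguous-character count, then by the lexicographically smallest tip
#' id. The procedure repeats on all subclades until no taxon duplication
#' remains, so the result carries at most one tip per taxon.
#'
#' @param clade A rooted `phylo` clade.
#' @param tm A [taxon_map()].
#' @param char_counts Optional named vector id -> unambiguous character
#'   count used for tie-breaking; absent ids count 0.
#' @return The pruned `phylo` tree (possibly a single tip). Removed tips
#'   and the duplication nodes at which they were pruned are recorded in
#'   the `"pruned"` attribute (data.frame `node`, `id`).
#' @export
prune_paralogs_rt <- function(clade, tm, char_counts = NULL) {
  ntip <- length(clade$tip.label)
  if (ntip <= 1L) {
    attr(clade, "pruned") <- data.frame(node = integer(), id = character())
    return(clade)
  }
  kids <- .children_list(clade)
  taxa <- taxon_of(tm, clade$tip.label)
  cc <- function(ids) {
    if (is.null(char_counts)) return(0)
    sum(char_counts[ids], na.rm = TRUE)
  }
  alive <- rep(TRUE, ntip)
  removed <- data.frame(node = integer(), id = character(),
                        stringsAsFactors = FALSE)
  tips_of <- function(v) {
    ix <- if (v <= ntip) v else phangorn::Descendants(clade, v, "tips")[[1L]]
    ix[alive[ix]]
  }
  visit <- function(v) {
    if (v <= ntip) return(invisible())
    repeat {
      ch <- kids[[v]]
      sets <- lapply(ch, function(k) unique(taxa[tips_of(k)]))
      nonempty <- lengths(sets) > 0L
      ch <- ch[nonempty]; sets <- sets[nonempty]
      if (length(ch) < 2L) break
      overlap <- NULL
      for (i in seq_along(ch)[-length(ch)]) {
        for (j in (i + 1L):length(ch)) {
          if (length(intersect(sets[[i]], sets[[j]]))) {
            overlap <- c(i, j); break
          }
        }
        if (!is.null(overlap)) break
      }
      if (is.null(overlap)) break
      i <- overlap[1L]; j <- overlap[2L]
      ni <- length(sets[[i]]); nj <- length(sets[[j]])
      loser <- if (ni < nj) i else if (nj < ni) j else {
        ids_i <- clade$tip.label[tips_of(ch[i])]
        ids_j <- clade$tip.label[tips_of(ch[j])]
        if (cc(ids_i) > cc(ids_j)) j
        else if (cc(ids_j) > cc(ids_i)) i
        else if (min(ids_i) <= min(ids_j)) j else i
      }
      lost_tips <- tips_of(ch[loser])
      alive[lost_tips] <<- FALSE
      removed <<- rbind(removed,
                        data.frame(node = v,
                                   id = clade$tip.label[lost_tips],
                                   stringsAsFactors = FALSE))
    }
    for (k in kids[[v]]) visit(k)
    invisible()
  }
  visit(ntip + 1L)
  out <- if (all(alive)) clade else
    .drop_tips(clade, clade$tip.label[!alive])
  out_taxa <- taxon_of(tm, out$tip.label)
  stopifnot(!anyDuplicated(out_taxa))
  attr(out, "pruned") <- removed
  out
}

#' Ortholog group container
#'
#' @param id Group identifier.
#' @param tree Pruned `phylo` tree with at most one tip per taxon.
#' @param alignment Trimmed alignment for the retained tips.
#' @param tm A [taxon_map()] (for the taxon count).
#' @return An object of class `ortholog_group` with fields `id`, `tree`,
#'   `alignment`, `n_taxa`, `n_cols`.
#' @export
ortholog_group <- function(id, tree, alignment, tm) {
  alignment <- as_alignment(alignment)
  taxa <- taxon_of(tm, rownames(alignment))
  if (anyDuplicated(taxa)) stop("duplicate taxon in ortholog group")
  structure(list(id = id, tree = tree, alignment = alignment,
                 n_taxa = length(unique(taxa)), n_cols = ncol(alignment)),
            class = "ortholog_group")
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat(sprintf("ortholog_group %s: %d taxa x %d columns\n",
              x$id, x$n_taxa, x$n_cols))
  invisible(x)
}

#' Build an ortholog group from a pruned clade
#'
#' Extracts the alignment rows of the retained tips from the homolog
#' alignment, trims columns at the ortholog occupancy threshold (default
#' 0.3), and rejects the group when it has fewer than `min_taxa` taxa or
#' `min_cols` columns after trimming.
#'
#' @param homolog The source [homolog_group()] (supplies the alignment).
#' @param pruned Pruned `phylo` tree from [prune_paralogs_rt()].
#' @param tm A [taxon_map()].
#' @param min_taxa Minimum number of taxa (inclusive).
#' @param min_cols Minimum number of alignment columns (inclusive).
#' @param min_occupancy Column-occupancy threshold for re-trimming.
#' @param id Identifier; defaults to the homolog id plus a serial suffix.
#' @return An [ortholog_group()], or a [rejected()] sentinel when the
#'   thresholds are not met.
#' @export
build_ortholog_group <- function(homolog, pruned, tm, min_taxa = 10,
                                 min_cols = 0, min_occupancy = 0.3,
                                 id = paste0(homolog$id, ".ortho")) {
  tips <- pruned$tip.label
  miss <- setdiff(tips, rownames(homolog$alignment))
  if (length(miss))
    stop("tip(s) without alignment row: ", paste(miss, collapse = ", "))
  aln <- homolog$alignment[tips, , drop = FALSE]
  aln <- trim_columns(aln, min_occupancy)
  og <- ortholog_group(id, pruned, aln, tm)
  if (og$n_taxa < min_taxa || og$n_cols < min_cols)
    return(rejected(sprintf("n_taxa %d < %d or n_cols %d < %d",
                            og$n_taxa, min_taxa, og$n_cols, min_cols)))
  og
}

#' Decompose one homolog group into ortholog groups
#'
#' Convenience wrapper: extracts root-taxon-rooted clades, prunes paralogs
#' from each, and builds ortholog groups.
#'
#' @inheritParams build_ortholog_group
#' @param homolog A curated [homolog_group()] with alignment and tree.
#' @return A list of [ortholog_group()]s.
#' @export
orthologs_from_homolog <- function(homolog, tm, min_taxa = 10,
                                   min_cols = 0, min_occupancy = 0.3) {
  clades <- extract_rooted_clades(homolog$tree, tm)
  cc <- count_unambiguous(homolog$alignment)
  out <- list()
  for (k in seq_along(clades)) {
    pruned <- prune_paralogs_rt(clades[[k]], tm, cc)
    og <- build_ortholog_group(homolog, pruned, tm, min_taxa, min_cols,
                               min_occupancy,
                               id = paste0(homolog$id, ".", k))
    if (!is_rejected(og)) out[[length(out) + 1L]] <- og
  }
  out
}
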