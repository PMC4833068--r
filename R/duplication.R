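# Locating gene and genome duplications: extract supported clades from
# homolog trees, detect nodes whose child subtrees share taxa, map them to
# species-tree branches, summarize per-branch duplication proportions, and
# rank gene-family expansions.

#' Clade extraction rule
#'
#' Defines which clades of a named taxon set are usable for duplication
#' mapping: the clade's tips must all belong to the member set, at least
#' `min_taxa_present` distinct member taxa must be present, and the mean
#' bootstrap support of the clade's internal nodes must reach
#' `min_mean_support`.
#'
#' @param clade_name Name of the taxon set.
#' @param members Character vector of member taxa.
#' @param min_taxa_present Minimum distinct member taxa, inclusive.
#' @param min_mean_support Minimum mean internal-node bootstrap percentage.
#' @return An object of class `clade_rule`.
#' @export
clade_rule <- function(clade_name, members, min_taxa_present,
                       min_mean_support = 80) {
  stopifnot(min_taxa_present <= length(members))
  structure(list(clade_name = clade_name, members = members,
                 min_taxa_present = min_taxa_present,
                 min_mean_support = min_mean_support),
            class = "clade_rule")
}

#' Extract well-supported clades of a taxon set from a homolog tree
#'
#' Roots the homolog tree at a tip outside the rule's member set (an
#' outgroup to the clade must be present), then returns every maximal
#' rooted clade whose tip taxa are all members of the rule's set, that
#' contains at least `min_taxa_present` distinct member taxa, and whose
#' mean internal-node bootstrap support is at least `min_mean_support`.
#' Mean support averages the internal nodes of the extracted clade only
#' (stem and tips excluded); a clade with fewer than one labeled internal
#' node is skipped.
#'
#' @param tree A `phylo` homolog tree with bootstrap supports as internal
#'   node labels.
#' @param rule A [clade_rule()].
#' @param tm A [taxon_map()].
#' @return A list of rooted `phylo` clades.
#' @export
extract_supported_clades <- function(tree, rule, tm) {
  taxa <- taxon_of(tm, tree$tip.label)
  member_tip <- taxa %in% rule$members
  if (!any(member_tip)) return(list())
  if (all(member_tip))
    stop("no outgroup to clade '", rule$clade_name, "' present in tree")
  if (is.null(tree$node.label) || all(is.na(node_supports(tree))))
    stop("bootstrap supports absent from tree")
  tr <- .reroot_at_tip(tree, tree$tip.label[which(!member_tip)[1L]])
  ntip <- length(tr$tip.label)
  taxa <- taxon_of(tm, tr$tip.label)
  member_tip <- taxa %in% rule$members
  desc <- phangorn::Descendants(tr, seq_len(ntip + tr$Nnode), "tips")
  pure <- vapply(desc, function(ix) all(member_tip[ix]), logical(1))
  par <- .parent_vec(tr)
  out <- list()
  for (v in seq_len(ntip + tr$Nnode)) {
    if (!pure[v]) next
    p <- par[v]
    if (!is.na(p) && pure[p]) next  # not maximal
    n_mem <- length(unique(taxa[desc[[v]]]))
    if (n_mem < rule$min_taxa_present) next
    cl <- extract_subtree(tr, v)
    sup <- node_supports(cl)
    sup <- sup[-1L]  # the clade root label belongs to the stem branch
    sup <- sup[!is.na(sup)]
    # a clade with no internal branches has no support to evaluate; it
    # passes vacuously (only possible when min_taxa_present <= 2)
    if (length(sup) && mean(sup) < rule$min_mean_support) next
    out[[length(out) + 1L]] <- cl
  }
  out
}

#' Detect gene duplication nodes in a rooted clade
#'
#' A duplication is recorded at every node whose child subtrees share at
#' least `min_shared` taxa (pairwise, at polytomies).
#'
#' @param clade A rooted `phylo` clade.
#' @param tm A [taxon_map()].
#' @param min_shared Minimum number of shared taxa between two children
#'   (default 2; single-taxon duplications are invisible by design).
#' @return A data.frame with one row per duplication: `node`,
#'   `shared_taxa` (semicolon-joined), `taxa_union` (semicolon-joined).
#' @export
detect_duplications <- function(clade, tm, min_shared = 2) {
  ntip <- length(clade$tip.label)
  out <- data.frame(node = integer(), shared_taxa = character(),
                    taxa_union = character(), stringsAsFactors = FALSE)
  if (ntip < 2L) return(out)
  taxa <- taxon_of(tm, clade$tip.label)
  kids <- .children_list(clade)
  desc <- phangorn::Descendants(clade, seq_len(ntip + clade$Nnode), "tips")
  taxa_of <- function(v) unique(taxa[desc[[v]]])
  for (v in (ntip + 1L):(ntip + clade$Nnode)) {
    ch <- kids[[v]]
    if (length(ch) < 2L) next
    sets <- lapply(ch, taxa_of)
    shared <- character(0)
    for (i in seq_along(ch)[-length(ch)])
      for (j in (i + 1L):length(ch))
        shared <- union(shared, intersect(sets[[i]], sets[[j]]))
    if (length(shared) >= min_shared) {
      out <- rbind(out, data.frame(
        node = v,
        shared_taxa = paste(sort(shared), collapse = ";"),
        taxa_union = paste(sort(unique(unlist(sets))), collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Map a duplication to a species-tree node
#'
#' Returns the most recent common ancestor, on the species tree, of all
#' taxa below the duplication node. When the gene clade conflicts with or
#' under-samples the species tree this is the containing (possibly
#' deeper) species node.
#'
#' @param taxa_union Character vector of taxa below the duplication node
#'   (or a semicolon-joined string as produced by
#'   [detect_duplications()]).
#' @param species_tree Rooted species `phylo` tree whose tips are taxon
#'   codes.
#' @return Species-tree node number.
#' @export
map_duplication <- function(taxa_union, species_tree) {
  if (length(taxa_union) == 1L && grepl(";", taxa_union))
    taxa_union <- strsplit(taxa_union, ";", fixed = TRUE)[[1L]]
  mrca_node(species_tree, taxa_union)
}

#' Keep one duplication per (extracted clade, species node)
#'
#' Nested duplications within one extracted clade that map to the same
#' species node are counted once. Idempotent.
#'
#' @param records Data.frame with columns `clade_serial` and
#'   `species_node` (other columns preserved from the first occurrence).
#' @return De-duplicated data.frame.
#' @export
dedupe_nested <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$clade_serial, records$species_node, sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Summarize duplication proportions per species-tree branch
#'
#' For each species-tree internal node (branch), the proportion is the
#' number of extracted clades with a duplication mapped there divided by
#' the number of informative clades. A clade is informative for a branch
#' when a duplication there would be observable in it: the clade's taxon
#' set contains at least two taxa from each child lineage of that species
#' node. Branches with zero informative clades are flagged "not
#' investigated". (The observability denominator is an explicit modeling
#' choice, recorded in the output.)
#'
#' @param records De-duplicated records (columns `clade_serial`,
#'   `species_node`).
#' @param clade_taxa List (by clade serial) of the taxon set of each
#'   extracted clade.
#' @param species_tree Rooted species `phylo` tree.
#' @param min_per_lineage Minimum taxa from each child lineage for a clade
#'   to be informative (default 2, matching `min_shared = 2`).
#' @return Data.frame with one row per internal species node: `node`,
#'   `n_dup`, `n_informative`, `proportion` (NA when not investigated),
#'   `investigated`.
#' @export
summarize_branches <- function(records, clade_taxa, species_tree,
                               min_per_lineage = 2) {
  ntip <- length(species_tree$tip.label)
  nodes <- (ntip + 1L):(ntip + species_tree$Nnode)
  kids <- .children_list(species_tree)
  desc <- phangorn::Descendants(species_tree,
                                seq_len(ntip + species_tree$Nnode), "tips")
  informative <- function(taxa, v) {
    for (ch in kids[[v]]) {
      below <- species_tree$tip.label[desc[[ch]]]
      if (sum(taxa %in% below) < min_per_lineage) return(FALSE)
    }
    TRUE
  }
  n_inf <- n_dup <- setNames(integer(length(nodes)), nodes)
  for (s in seq_along(clade_taxa)) {
    taxa <- clade_taxa[[s]]
    for (i in seq_along(nodes)) {
      if (informative(taxa, nodes[i])) n_inf[i] <- n_inf[i] + 1L
    }
  }
  if (nrow(records)) {
    tab <- table(factor(records$species_node, levels = nodes))
    n_dup <- n_dup + as.integer(tab)
  }
  data.frame(node = nodes, n_dup = as.integer(n_dup),
             n_informative = as.integer(n_inf),
             proportion = ifelse(n_inf > 0, n_dup / pmax(n_inf, 1L), NA_real_),
             investigated = n_inf > 0L)
}

#' Run duplication mapping across homolog trees
#'
#' Extracts supported clades from every homolog tree under the rule,
#' detects duplications, maps them to the species tree, de-duplicates
#' nested events per extracted clade, and summarizes per-branch
#' proportions.
#'
#' @param trees List of homolog `phylo` trees with bootstrap supports.
#' @param rule A [clade_rule()].
#' @param species_tree Rooted species `phylo` tree.
#' @param tm A [taxon_map()].
#' @param min_shared Minimum shared taxa for a duplication (default 2).
#' @return List with `records` (de-duplicated duplication records),
#'   `summary` (per-branch data.frame from [summarize_branches()]), and
#'   `n_clades` (number of extracted clades).
#' @export
map_duplications_study <- function(trees, rule, species_tree, tm,
                                   min_shared = 2) {
  records <- data.frame(clade_serial = integer(), species_node = integer(),
                        node = integer(), shared_taxa = character(),
                        taxa_union = character(), stringsAsFactors = FALSE)
  clade_taxa <- list()
  serial <- 0L
  for (tr in trees) {
    clades <- tryCatch(extract_supported_clades(tr, rule, tm),
                       error = function(e) list())
    for (cl in clades) {
      serial <- serial + 1L
      clade_taxa[[serial]] <- unique(taxon_of(tm, cl$tip.label))
      dups <- detect_duplications(cl, tm, min_shared)
      if (nrow(dups)) {
        dups$species_node <- vapply(dups$taxa_union, map_duplication,
                                    integer(1), species_tree = species_tree,
                                    USE.NAMES = FALSE)
        dups$clade_serial <- serial
        records <- rbind(records,
                         dups[, c("clade_serial", "species_node", "node",
                                  "shared_taxa", "taxa_union")])
      }
    }
  }
  records <- dedupe_nested(records)
  list(records = records,
       summary = summarize_branches(records, clade_taxa, species_tree,
                                    min_per_lineage = min_shared),
       n_clades = serial)
}

#' Rank extracted clades by gene-family expansion
#'
#' Ranks clades with at least `min_taxa` distinct taxa two ways: table A
#' by the highest tip count of any single taxon (descending), table B by
#' the total number of tips (descending).
#'
#' @param clades List of `phylo` clades.
#' @param tm A [taxon_map()].
#' @param min_taxa Minimum distinct taxa per clade (default 5).
#' @param ids Optional clade identifiers (defaults to positions).
#' @return List of two data.frames `by_single_taxon` and `by_total_tips`,
#'   each with columns `clade_id`, `n_tips`, `n_taxa`, `top_taxon`,
#'   `top_count`.
#' @export
rank_expansion <- function(clades, tm, min_taxa = 5,
                           ids = as.character(seq_along(clades))) {
  rows <- lapply(seq_along(clades), function(k) {
    taxa <- taxon_of(tm, clades[[k]]$tip.label)
    counts <- sort(table(taxa), decreasing = TRUE)
    data.frame(clade_id = ids[k], n_tips = length(taxa),
               n_taxa = length(counts),
               top_taxon = names(counts)[1L],
               top_count = as.integer(counts[1L]),
               stringsAsFactors = FALSE)
  })
  empty <- data.frame(clade_id = character(), n_tips = integer(),
                      n_taxa = integer(), top_taxon = character(),
                      top_count = integer(), stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(list(by_single_taxon = empty,
                                      by_total_tips = empty))
  df <- do.call(rbind, rows)
  df <- df[df$n_taxa >= min_taxa, , drop = FALSE]
  a <- df[order(-df$top_count, df$clade_id), , drop = FALSE]
  b <- df[order(-df$n_tips, df$clade_id), , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  list(by_single_taxon = a, by_total_tips = b)
}
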