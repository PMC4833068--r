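# Shared fixtures, built in code.

# taxon map for single-letter taxa (ids like "A@1"); every taxon ingroup
# except an optional root taxon
letter_tm <- function(taxa, root_taxon = NULL, habit = NULL) {
  taxa <- union(taxa, root_taxon)
  ingroup <- setdiff(taxa, root_taxon)
  taxon_map(taxa, ingroup = ingroup, habit = habit,
            root_taxon = root_taxon, delimiter = "@")
}

# random rooted tree with n tips labeled "t1".."tn" and exponential
# branch lengths
random_tree <- function(n, mean_len = 0.1) {
  tr <- ape::rtree(n, br = function(k) stats::rexp(k, 1 / mean_len))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# brute-force MRCA: deepest node whose tip set contains all query tips
brute_mrca <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  best <- NA_integer_
  best_depth <- -1
  depth <- function(v) {
    d <- 0
    repeat {
      i <- match(v, tree$edge[, 2])
      if (is.na(i)) return(d)
      v <- tree$edge[i, 1]
      d <- d + 1
    }
  }
  for (v in seq_len(ntip + tree$Nnode)) {
    below <- if (v <= ntip) tree$tip.label[v] else
      tree$tip.label[phangorn::Descendants(tree, v, "tips")[[1]]]
    if (all(tips %in% below)) {
      d <- depth(v)
      if (d > best_depth) {
        best <- v
        best_depth <- d
      }
    }
  }
  best
}

# independent recursive oracle for the stepwise average (plain recursion
# on a parent lookup, no package internals)
oracle_stepwise <- function(tree, node, lengths = tree$edge.length) {
  children <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  rec <- function(v) {
    ch <- children(v)
    if (length(ch) == 0) return(0)
    mean(sapply(ch, function(k)
      lengths[which(tree$edge[, 2] == k)] + rec(k)))
  }
  rec(node)
}

# a small aligned homolog group over the given tree, all residues
# unambiguous so char counts equal alignment width
uniform_group <- function(id, tree, width = 150) {
  members <- setNames(rep(strrep("A", width), length(tree$tip.label)),
                      tree$tip.label)
  homolog_group(id, members, alignment = members, tree = tree)
}
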