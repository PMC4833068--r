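#' @importFrom ape read.tree write.tree getMRCA extract.clade drop.tip Ntip
#'   Nnode is.rooted root unroot
#' @importFrom phangorn Descendants Ancestors
#' @importFrom stats median rbinom rexp rlnorm runif setNames
#' @importFrom utils read.table write.table head
NULL

# ---- internal tree helpers ----------------------------------------------

.n_tips <- function(tree) length(tree$tip.label)

#' @noRd
.children_list <- function(tree) {
  n <- .n_tips(tree) + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    out[[p]] <- c(out[[p]], tree$edge[i, 2L])
  }
  out
}

#' @noRd
.parent_vec <- function(tree) {
  n <- .n_tips(tree) + tree$Nnode
  par <- rep(NA_integer_, n)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

#' Tip labels below a node
#' @noRd
.tips_under <- function(tree, node) {
  if (node <= .n_tips(tree)) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1L]]]
}

#' Edge row index of the edge subtending `node` (NA at the root)
#' @noRd
.edge_to <- function(tree, node) {
  i <- match(node, tree$edge[, 2L])
  i
}

#' Branch length of the edge subtending `node`; 0 when absent
#' @noRd
.stem_length <- function(tree, node) {
  i <- .edge_to(tree, node)
  if (is.na(i) || is.null(tree$edge.length)) 0 else tree$edge.length[i]
}

.root_node <- function(tree) .n_tips(tree) + 1L

# ---- newick I/O ----------------------------------------------------------

#' Read a newick tree
#'
#' Parses a newick string (or file) into an [ape::read.tree()] `phylo`
#' object. Internal node labels are retained verbatim in `node.label`;
#' numeric labels are interpreted as bootstrap support percentages (see
#' [node_supports()]). A `comment` support style accepts supports written
#' as square-bracket comments after the closing parenthesis, e.g.
#' `"((A,B)[95],C);"`.
#'
#' @param text Newick string. Exactly one of `text`/`file` must be given.
#' @param file Path to a newick file (first tree used).
#' @param support_style `"label"` (default; ML-tree style internal-node
#'   labels) or `"comment"` (square-bracket comments).
#' @return A `phylo` object. Polytomies are preserved.
#' @export
read_newick <- function(text = NULL, file = NULL,
                        support_style = c("label", "comment")) {
  support_style <- match.arg(support_style)
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'", n_open, n_close))
  if (support_style == "comment")
    text <- gsub("\\)\\[([0-9.]+)\\]", ")\\1", text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("newick parse failure")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  tree
}

#' Serialize a tree to newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Bootstrap supports of internal nodes
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode`; `NA` where the node label
#'   is absent or non-numeric. Values are bootstrap percentages in
#'   \[0, 100\].
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

# ---- tree surgery --------------------------------------------------------

#' Extract the subtree rooted at a node
#'
#' Deep copy of the clade below `node`. The stem branch length of the
#' clade is retained as the returned tree's `root.edge`. A tip node yields
#' a single-tip tree.
#'
#' @param tree A rooted `phylo` object.
#' @param node Node number (tips are `1..Ntip`, internals follow).
#' @return A `phylo` object.
#' @export
extract_subtree <- function(tree, node) {
  n_all <- .n_tips(tree) + tree$Nnode
  if (!is.numeric(node) || length(node) != 1L || node < 1L || node > n_all)
    stop("node not in tree: ", node)
  stem <- .stem_length(tree, node)
  if (node <= .n_tips(tree)) {
    out <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      tip.label = tree$tip.label[node],
      edge.length = stem,
      Nnode = 1L), class = "phylo")
    attr(out, "order") <- "cladewise"
    return(out)
  }
  if (node == .root_node(tree)) {
    out <- tree
  } else {
    out <- ape::extract.clade(tree, node)
  }
  out$root.edge <- stem
  out
}

#' Most recent common ancestor of a set of tips
#'
#' Returns the deepest node whose descendant tip set contains every given
#' tip label. A single label returns the tip node itself.
#'
#' @param tree A rooted `phylo` object.
#' @param tips Character vector of tip labels (or a set of taxon codes when
#'   the tree's tips are taxa, as in a species tree).
#' @return Node number.
#' @export
mrca_node <- function(tree, tips) {
  tips <- unique(as.character(tips))
  if (length(tips) == 0L) stop("empty tip set")
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss))
    stop("tip(s) absent from tree: ", paste(miss, collapse = ", "))
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' Suppress unary internal nodes, merging branch lengths additively
#' @noRd
.suppress_unary <- function(tree) {
  if (.n_tips(tree) < 2L) return(tree)
  ape::collapse.singles(tree)
}

#' Re-root a tree at an arbitrary edge/tip (used for rooting-invariance
#' tests and for clade extraction from unrooted trees)
#' @noRd
.reroot_at_tip <- function(tree, tip_label) {
  ape::root(tree, outgroup = tip_label, resolve.root = TRUE)
}

# ---- sequences and alignments --------------------------------------------

#' Characters treated as gaps/ambiguities in occupancy and character counts
#' @noRd
.GAPCHARS <- c("-", "X", "x", "*", "?", ".")

#' Read a FASTA file into a named character vector
#'
#' @param file Path to a FASTA file (amino acid or nucleotide).
#' @return Named character vector of residue strings.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readBStringSet(file)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA, wrapped at 80 columns
#'
#' @param seqs Named character vector of residue strings.
#' @param file Output path.
#' @export
write_fasta <- function(seqs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  invisible(file)
}

#' Convert named residue strings to an alignment matrix
#'
#' Rows are sequences (rownames = ids), columns are alignment positions,
#' cells are single characters. All rows must have equal length.
#'
#' @param seqs Named character vector of equal-length strings.
#' @return Character matrix.
#' @export
as_alignment <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  if (length(seqs) == 0L) stop("empty alignment")
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("alignment rows have unequal lengths: ",
         paste(unique(w), collapse = ", "))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' Collapse an alignment matrix back to named strings
#'
#' @param aln Character matrix as produced by [as_alignment()].
#' @return Named character vector.
#' @export
aln_strings <- function(aln) {
  out <- apply(aln, 1L, paste, collapse = "")
  if (length(out) == 0) out <- character(0)
  setNames(as.character(out), rownames(aln))
}

#' Count unambiguous characters per aligned sequence
#'
#' Counts cells that are neither gaps nor ambiguity symbols
#' (`-`, `X`, `*`, `?`, `.`). This is the "number of characters in the
#' trimmed alignment" used to choose isoform representatives.
#'
#' @param aln Character matrix or named character vector of strings.
#' @return Named integer vector (by sequence id).
#' @export
count_unambiguous <- function(aln) {
  aln <- as_alignment(aln)
  ok <- !(aln %in% .GAPCHARS)
  dim(ok) <- dim(aln)
  setNames(as.integer(rowSums(ok)), rownames(aln))
}

# ---- taxon map -----------------------------------------------------------

#' Derive taxon codes from sequence ids
#'
#' The taxon code is the substring of the sequence id before the first
#' occurrence of `delimiter` (default `"@"`). Ids lacking the delimiter are
#' their own taxon code.
#'
#' @param ids Character vector of sequence ids.
#' @param delimiter Single character separating taxon code from the rest.
#' @return Character vector of taxon codes.
#' @export
seq_taxon <- function(ids, delimiter = "@") {
  sub(paste0("\\Q", delimiter, "\\E.*$"), "", ids)
}

#' Construct a taxon map
#'
#' Bundles the id-to-taxon rule with per-taxon metadata: ingroup membership,
#' growth habit (woody/herbaceous), named clade sets, and the single
#' outgroup taxon used for rooting homolog trees.
#'
#' @param taxa Character vector of taxon codes, or a data.frame with columns
#'   `taxon`, `ingroup` (logical), `habit` (`"W"`, `"H"` or `NA`).
#' @param ingroup Character vector of ingroup taxon codes (ignored when
#'   `taxa` is a data.frame).
#' @param habit Named character vector taxon -> `"W"`/`"H"` (optional).
#' @param clades Named list of character vectors: clade name -> taxon set.
#' @param root_taxon The taxon used to root homolog trees; must not be an
#'   ingroup taxon.
#' @param delimiter Id-to-taxon delimiter, see [seq_taxon()].
#' @return An object of class `taxon_map`.
#' @export
taxon_map <- function(taxa, ingroup = character(), habit = NULL,
                      clades = list(), root_taxon = NULL, delimiter = "@") {
  if (is.data.frame(taxa)) {
    df <- taxa
    stopifnot(all(c("taxon", "ingroup") %in% names(df)))
    if (is.null(df$habit)) df$habit <- NA_character_
  } else {
    df <- data.frame(taxon = as.character(taxa),
                     ingroup = taxa %in% ingroup,
                     habit = NA_character_,
                     stringsAsFactors = FALSE)
    if (!is.null(habit)) df$habit[match(names(habit), df$taxon)] <- habit
  }
  if (anyDuplicated(df$taxon)) stop("duplicate taxon codes")
  if (!is.null(root_taxon)) {
    if (!root_taxon %in% df$taxon)
      stop("root_taxon not in taxon table: ", root_taxon)
    if (df$ingroup[match(root_taxon, df$taxon)])
      stop("root_taxon must be an outgroup: ", root_taxon)
  }
  structure(list(taxa = df, clades = clades, root_taxon = root_taxon,
                 delimiter = delimiter),
            class = "taxon_map")
}

#' @export
print.taxon_map <- function(x, ...) {
  cat(sprintf("taxon_map: %d taxa (%d ingroup), root taxon %s, %d clade set(s)\n",
              nrow(x$taxa), sum(x$taxa$ingroup),
              if (is.null(x$root_taxon)) "<none>" else x$root_taxon,
              length(x$clades)))
  invisible(x)
}

#' Taxon codes for sequence ids under a taxon map
#'
#' @param tm A [taxon_map()].
#' @param ids Sequence ids.
#' @return Character vector of taxon codes.
#' @export
taxon_of <- function(tm, ids) seq_taxon(ids, tm$delimiter)

#' Ingroup taxa of a taxon map
#' @param tm A [taxon_map()].
#' @return Character vector.
#' @export
ingroup_taxa <- function(tm) tm$taxa$taxon[tm$taxa$ingroup]

#' Habit (woody/herbaceous) lookup
#' @param tm A [taxon_map()].
#' @param taxa Taxon codes.
#' @return Character vector of `"W"`, `"H"` or `NA`.
#' @export
habit_of <- function(tm, taxa) tm$taxa$habit[match(taxa, tm$taxa$taxon)]

#' Read/write a taxon map as TSV
#'
#' The main table is 3+ columns (`taxon`, `ingroup`, `habit`); clade sets
#' are a separate 2-column TSV (`clade`, `taxon`).
#'
#' @param file Path to the taxon table TSV.
#' @param clade_file Optional path to the clade-set TSV.
#' @param root_taxon Root taxon code.
#' @param delimiter Id-to-taxon delimiter.
#' @return A [taxon_map()].
#' @export
read_taxon_map <- function(file, clade_file = NULL, root_taxon = NULL,
                           delimiter = "@") {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$ingroup <- as.logical(df$ingroup)
  clades <- list()
  if (!is.null(clade_file)) {
    cd <- utils::read.table(clade_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    clades <- split(cd$taxon, cd$clade)
  }
  taxon_map(df, clades = clades, root_taxon = root_taxon,
            delimiter = delimiter)
}

#' @rdname read_taxon_map
#' @param tm A [taxon_map()].
#' @export
write_taxon_map <- function(tm, file, clade_file = NULL) {
  utils::write.table(tm$taxa, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(clade_file) && length(tm$clades)) {
    cd <- data.frame(clade = rep(names(tm$clades), lengths(tm$clades)),
                     taxon = unlist(tm$clades, use.names = FALSE))
    utils::write.table(cd, clade_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}
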