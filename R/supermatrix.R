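# Supermatrix construction: ortholog filtering, concatenation with
# partition bookkeeping and occupancy statistics, gene-wise jackknife.

#' Filter ortholog groups by taxon and column counts
#'
#' @param groups List of [ortholog_group()]s.
#' @param min_taxa Minimum number of taxa (inclusive).
#' @param min_cols Minimum number of alignment columns (inclusive).
#' @return The subset of `groups` meeting both thresholds.
#' @export
filter_orthologs <- function(groups, min_taxa, min_cols) {
  keep <- vapply(groups, function(g)
    g$n_taxa >= min_taxa && g$n_cols >= min_cols, logical(1))
  groups[keep]
}

#' Concatenate ortholog alignments into a partitioned supermatrix
#'
#' Taxa absent from a gene receive all-gap rows for that partition.
#' Partition coordinates are 1-based inclusive. Occupancy statistics:
#' gene occupancy is the fraction of filled (taxon, gene) cells over
#' n_taxa x n_genes; character occupancy is the fraction of non-gap,
#' non-ambiguity characters over n_taxa x total columns. Both definitions
#' are recorded in the object and in written output headers.
#'
#' @param groups Non-empty list of [ortholog_group()]s.
#' @param tm A [taxon_map()] (maps alignment row ids to taxa; supermatrix
#'   rows are named by taxon).
#' @return An object of class `supermatrix` with fields `alignment`
#'   (character matrix, rows = taxa), `partitions` (data.frame `gene`,
#'   `start`, `end`), `gene_occupancy`, `character_occupancy`,
#'   `per_taxon_gene_fraction`, `presence` (taxon x gene logical matrix).
#' @export
concatenate <- function(groups, tm) {
  if (length(groups) == 0L) stop("no ortholog groups to concatenate")
  gene_ids <- vapply(groups, function(g) g$id, character(1))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  taxa_per <- lapply(groups, function(g) {
    tx <- taxon_of(tm, rownames(g$alignment))
    if (anyDuplicated(tx))
      stop("duplicate taxon within group ", g$id)
    tx
  })
  taxa <- sort(unique(unlist(taxa_per)))
  widths <- vapply(groups, function(g) ncol(g$alignment), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  total <- sum(widths)
  m <- matrix("-", nrow = length(taxa), ncol = total,
              dimnames = list(taxa, NULL))
  presence <- matrix(FALSE, nrow = length(taxa), ncol = length(groups),
                     dimnames = list(taxa, gene_ids))
  for (k in seq_along(groups)) {
    aln <- groups[[k]]$alignment
    rows <- match(taxa_per[[k]], taxa)
    m[rows, starts[k]:ends[k]] <- aln
    presence[rows, k] <- TRUE
  }
  filled <- !(m %in% .GAPCHARS)
  dim(filled) <- dim(m)
  structure(list(
    alignment = m,
    partitions = data.frame(gene = gene_ids, start = starts, end = ends,
                            stringsAsFactors = FALSE),
    gene_occupancy = mean(presence),
    character_occupancy = mean(filled),
    per_taxon_gene_fraction = setNames(rowMeans(presence), taxa),
    presence = presence), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf(
    "supermatrix: %d taxa x %d characters, %d genes; gene occupancy %.1f%%, character occupancy %.1f%%\n",
    nrow(x$alignment), ncol(x$alignment), nrow(x$partitions),
    100 * x$gene_occupancy, 100 * x$character_occupancy))
  invisible(x)
}

#' Recover the per-gene alignments from a supermatrix
#'
#' Splits the supermatrix by its partitions and, for each gene, drops the
#' all-gap padding rows of taxa absent from that gene.
#'
#' @param sm A [concatenate()] result.
#' @return Named list (by gene id) of character matrices.
#' @export
deconcatenate <- function(sm) {
  out <- vector("list", nrow(sm$partitions))
  names(out) <- sm$partitions$gene
  for (k in seq_len(nrow(sm$partitions))) {
    cols <- sm$partitions$start[k]:sm$partitions$end[k]
    rows <- sm$presence[, k]
    out[[k]] <- sm$alignment[rows, cols, drop = FALSE]
  }
  out
}

#' Gene-wise jackknife replicates of a supermatrix
#'
#' Each replicate keeps `round(fraction * n_genes)` whole gene partitions
#' sampled without replacement; gene regions are never split. Reproducible
#' from `seed`.
#'
#' @param sm A [concatenate()] result.
#' @param fraction Fraction of genes per replicate, in (0, 1).
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return List of `supermatrix` objects; each carries the sampled gene
#'   ids in its `"genes"` attribute. The manifest (replicate x gene) is
#'   attached to the list as attribute `"manifest"`.
#' @export
jackknife_genes <- function(sm, fraction, n_reps, seed) {
  stopifnot(fraction > 0, fraction < 1)
  n_genes <- nrow(sm$partitions)
  k <- round(fraction * n_genes)
  if (k < 1L) stop("fraction yields 0 genes")
  picks <- .with_seed(seed, lapply(seq_len(n_reps), function(r)
    sort(sample.int(n_genes, k))))
  reps <- vector("list", n_reps)
  manifest <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    pick <- picks[[r]]
    genes <- sm$partitions$gene[pick]
    manifest[[r]] <- genes
    cols <- unlist(lapply(pick, function(i)
      sm$partitions$start[i]:sm$partitions$end[i]))
    widths <- sm$partitions$end[pick] - sm$partitions$start[pick] + 1L
    ends <- cumsum(widths)
    m <- sm$alignment[, cols, drop = FALSE]
    filled <- !(m %in% .GAPCHARS)
    dim(filled) <- dim(m)
    pres <- sm$presence[, pick, drop = FALSE]
    rep_sm <- structure(list(
      alignment = m,
      partitions = data.frame(gene = genes,
                              start = c(1L, head(ends, -1L) + 1L),
                              end = ends, stringsAsFactors = FALSE),
      gene_occupancy = mean(pres),
      character_occupancy = mean(filled),
      per_taxon_gene_fraction = rowMeans(pres),
      presence = pres), class = "supermatrix")
    attr(rep_sm, "genes") <- genes
    reps[[r]] <- rep_sm
  }
  attr(reps, "manifest") <- manifest
  attr(reps, "seed") <- seed
  reps
}

#' Write a supermatrix to FASTA, relaxed phylip, and a partition file
#'
#' The partition file follows the RAxML style
#' `"WAG, <gene> = <start>-<end>"`; the occupancy TSV reports per-taxon
#' gene fractions. Model metadata is emitted only; model fitting is
#' external.
#'
#' @param sm A [concatenate()] result.
#' @param prefix Output path prefix; files `<prefix>.fasta`,
#'   `<prefix>.phy`, `<prefix>.partitions.txt`, `<prefix>.occupancy.tsv`
#'   are written.
#' @param model Substitution model name for the partition file.
#' @return Invisibly, the vector of written paths.
#' @export
write_supermatrix <- function(sm, prefix, model = "WAG") {
  seqs <- aln_strings(sm$alignment)
  f_fa <- paste0(prefix, ".fasta")
  write_fasta(seqs, f_fa)
  f_phy <- paste0(prefix, ".phy")
  con <- file(f_phy, "w")
  writeLines(sprintf("%d %d", nrow(sm$alignment), ncol(sm$alignment)), con)
  pad <- max(nchar(names(seqs))) + 2L
  writeLines(sprintf(paste0("%-", pad, "s%s"), names(seqs), seqs), con)
  close(con)
  f_part <- paste0(prefix, ".partitions.txt")
  writeLines(sprintf("%s, %s = %d-%d", model, sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end), f_part)
  f_occ <- paste0(prefix, ".occupancy.tsv")
  con <- file(f_occ, "w")
  writeLines(c(
    "# gene occupancy = filled (taxon,gene) cells / (n_taxa x n_genes)",
    "# character occupancy = non-gap characters / (n_taxa x total columns)",
    sprintf("# gene_occupancy\t%.6f", sm$gene_occupancy),
    sprintf("# character_occupancy\t%.6f", sm$character_occupancy),
    "taxon\tgene_fraction"), con)
  writeLines(sprintf("%s\t%.6f", names(sm$per_taxon_gene_fraction),
                     sm$per_taxon_gene_fraction), con)
  close(con)
  invisible(c(f_fa, f_phy, f_part, f_occ))
}
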