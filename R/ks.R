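# Within-taxon Ks distributions: self-hit filtering, Nei-Gojobori (1986)
# synonymous/nonsynonymous distances on pairwise codon alignments, and
# fixed-edge histograms for WGD-peak inspection.

#' Standard genetic code as a codon -> amino acid lookup
#' @noRd
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# cache of per-codon synonymous site counts
.ng_env <- new.env(parent = emptyenv())

#' Per-codon synonymous site counts under NG86
#'
#' For each sense codon, the synonymous site count is the sum over its
#' three positions of the fraction of the three possible nucleotide
#' changes that preserve the amino acid; changes producing stop codons
#' count as nonsynonymous.
#' @noRd
.codon_syn_sites <- function() {
  if (!is.null(.ng_env$syn_sites)) return(.ng_env$syn_sites)
  code <- .genetic_code()
  nts <- c("A", "C", "G", "T")
  codons <- names(code)
  s <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (code[cd] == "*") { s[cd] <- NA_real_; next }
    chars <- strsplit(cd, "")[[1L]]
    tot <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nts, chars[pos])) {
        alt <- chars
        alt[pos] <- nt
        alt_cd <- paste(alt, collapse = "")
        if (code[alt_cd] != "*" && code[alt_cd] == code[cd])
          tot <- tot + 1 / 3
      }
    }
    s[cd] <- tot
  }
  .ng_env$syn_sites <- s
  s
}

#' Synonymous/nonsynonymous difference counts between two codons,
#' averaged over all orderings of single-nucleotide steps; paths through
#' stop codons are excluded (all paths used if none avoids a stop).
#' @noRd
.codon_path_diffs <- function(c1, c2) {
  code <- .genetic_code()
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd,
                  list(pos),
                  list(pos, rev(pos)),
                  {
                    p <- pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  eval_path <- function(order) {
    cur <- strsplit(c1, "")[[1L]]
    tgt <- strsplit(c2, "")[[1L]]
    sd <- 0; ndf <- 0
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (code[nxt] == "*" && nxt != c2) return(NULL)  # via a stop codon
      if (code[prev] == code[nxt]) sd <- sd + 1 else ndf <- ndf + 1
    }
    c(sd = sd, nd = ndf)
  }
  res <- Filter(Negate(is.null), lapply(perms, eval_path))
  if (length(res) == 0L) {
    res <- lapply(perms, function(order) {
      cur <- strsplit(c1, "")[[1L]]
      tgt <- strsplit(c2, "")[[1L]]
      sd <- 0; ndf <- 0
      for (p in order) {
        prev <- paste(cur, collapse = "")
        cur[p] <- tgt[p]
        nxt <- paste(cur, collapse = "")
        if (code[prev] == code[nxt]) sd <- sd + 1 else ndf <- ndf + 1
      }
      c(sd = sd, nd = ndf)
    })
  }
  colMeans(do.call(rbind, res))
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous distances
#'
#' Computes Ka and Ks for a two-sequence codon alignment by the NG86
#' counting method: per-codon synonymous site counts averaged over the two
#' sequences; differences at codons differing at more than one position
#' averaged with equal weight over all orderings of single-nucleotide
#' steps (paths through stop codons excluded); proportions corrected for
#' multiple substitutions with d = -(3/4) ln(1 - (4/3) p). Codon columns
#' containing a gap or non-ACGT symbol in either sequence are dropped
#' before counting.
#'
#' @param codon_aln Two-row codon alignment (matrix or named strings);
#'   width divisible by 3.
#' @return List with `ka`, `ks` (NA when saturated), `pn`, `ps`, `S`, `N`
#'   (site counts), `sd`, `nd` (difference counts), `n_codons` (codons
#'   compared), `saturated_ks`, `saturated_ka`.
#' @export
ng86 <- function(codon_aln) {
  aln <- as_alignment(codon_aln)
  if (nrow(aln) != 2L) stop("ng86 requires exactly two sequences")
  if (ncol(aln) %% 3L != 0L) stop("codon alignment width not divisible by 3")
  aln <- toupper(aln)
  n_codon <- ncol(aln) %/% 3L
  code <- .genetic_code()
  syn_sites <- .codon_syn_sites()
  c1 <- character(0); c2 <- character(0)
  for (k in seq_len(n_codon)) {
    cols <- (3L * (k - 1L) + 1L):(3L * k)
    a <- paste(aln[1L, cols], collapse = "")
    b <- paste(aln[2L, cols], collapse = "")
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) next
    if (code[a] == "*" || code[b] == "*")
      stop(sprintf("internal stop codon at codon %d (%s/%s)", k, a, b))
    c1 <- c(c1, a); c2 <- c(c2, b)
  }
  if (length(c1) == 0L) stop("no comparable codons")
  S <- (sum(syn_sites[c1]) + sum(syn_sites[c2])) / 2
  N <- 3 * length(c1) - S
  sd_tot <- 0; nd_tot <- 0
  for (k in seq_along(c1)) {
    if (c1[k] == c2[k]) next
    d <- .codon_path_diffs(c1[k], c2[k])
    sd_tot <- sd_tot + d[["sd"]]
    nd_tot <- nd_tot + d[["nd"]]
  }
  ps <- if (S > 0) sd_tot / S else 0
  pn <- if (N > 0) nd_tot / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p) + 0  # + 0 normalizes IEEE negative zero
  }
  ks <- jc(ps); ka <- jc(pn)
  list(ka = ka, ks = ks, pn = pn, ps = ps, S = S, N = N,
       sd = sd_tot, nd = nd_tot, n_codons = length(c1),
       saturated_ks = is.na(ks), saturated_ka = is.na(ka))
}

# ---- self-hit filtering --------------------------------------------------

#' Filter within-taxon self-hit reports into paralog pairs
#'
#' Drops self matches, deduplicates unordered pairs, removes hits with
#' percent identity below `min_pident` or fewer than `min_nident`
#' identical aligned residues, then removes every sequence participating
#' in `max_hits` or more remaining hits (with all its pairs) to avoid
#' over-representing families with many recent duplicates. Hits are
#' counted after thresholding by default (`count = "pre"` counts before).
#' The operation is idempotent.
#'
#' @param hits Data.frame with columns `query`, `subject`, `pident`,
#'   `nident` (e.g. from [read_hit_table()]).
#' @param min_pident Minimum percent identity, inclusive (default 20).
#' @param min_nident Minimum identical residues, inclusive (default 50).
#' @param max_hits Hit-count threshold at which a sequence is removed
#'   (default 10, i.e. sequences with 10 or more hits are dropped).
#' @param count Whether the hit count is taken after (`"post"`, default)
#'   or before (`"pre"`) the identity thresholds.
#' @return Data.frame of retained paralog pairs (`id1`, `id2`, `pident`,
#'   `nident`), each unordered pair once with `id1 < id2`.
#' @export
filter_self_hits <- function(hits, min_pident = 20, min_nident = 50,
                             max_hits = 10, count = c("post", "pre")) {
  count <- match.arg(count)
  df <- hits[hits$query != hits$subject, , drop = FALSE]
  df <- data.frame(id1 = pmin(df$query, df$subject),
                   id2 = pmax(df$query, df$subject),
                   pident = df$pident, nident = df$nident,
                   stringsAsFactors = FALSE)
  dedupe <- function(d) d[!duplicated(paste(d$id1, d$id2, sep = "\r")), ,
                          drop = FALSE]
  pass <- dedupe(df[df$pident >= min_pident & df$nident >= min_nident, ,
                    drop = FALSE])
  counted <- if (count == "post") pass else dedupe(df)
  tab <- table(c(counted$id1, counted$id2))
  too_many <- names(tab)[tab >= max_hits]
  out <- pass[!(pass$id1 %in% too_many) & !(pass$id2 %in% too_many), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- histogram -----------------------------------------------------------

#' Fixed-edge Ks histogram
#'
#' Bins Ks values on a fixed grid (default width 0.05 on \[0, 2\], which
#' resolves typical paralog peaks between 0.3 and 1 as well as the deep
#' peak near 1.8-2). Values outside the range (and saturated NA values)
#' are counted in an overflow bucket.
#'
#' @param values Numeric Ks values (NA allowed).
#' @param bin_width Bin width (default 0.05).
#' @param range Two-element range (default `c(0, 2)`).
#' @param taxon Optional taxon code carried in the result.
#' @return An object of class `ks_distribution`: list with `taxon`,
#'   `values`, `breaks`, `counts`, `overflow`.
#' @export
ks_histogram <- function(values, bin_width = 0.05, range = c(0, 2),
                         taxon = NA_character_) {
  stopifnot(bin_width > 0, length(range) == 2L, range[2L] > range[1L])
  breaks <- seq(range[1L], range[2L], by = bin_width)
  if (breaks[length(breaks)] < range[2L]) breaks <- c(breaks, range[2L])
  v <- values[!is.na(values)]
  inside <- v >= range[1L] & v < range[2L]
  counts <- integer(length(breaks) - 1L)
  if (any(inside)) {
    ix <- pmin(findInterval(v[inside], breaks), length(counts))
    tab <- tabulate(ix, nbins = length(counts))
    counts <- as.integer(tab)
  }
  structure(list(taxon = taxon, values = values, breaks = breaks,
                 counts = counts,
                 overflow = sum(!inside) + sum(is.na(values))),
            class = "ks_distribution")
}

#' @export
print.ks_distribution <- function(x, ...) {
  modal <- which.max(x$counts)
  cat(sprintf(
    "ks_distribution%s: %d values, modal bin [%.2f, %.2f) (n = %d), %d outside range\n",
    if (is.na(x$taxon)) "" else paste0(" for ", x$taxon),
    length(x$values), x$breaks[modal], x$breaks[modal + 1L],
    x$counts[modal], x$overflow))
  invisible(x)
}

# ---- pipeline ------------------------------------------------------------

#' Global pairwise protein alignment
#'
#' Built-in aligner for paralog-pair preparation (Needleman-Wunsch with
#' BLOSUM62, affine gaps); precomputed alignments can be supplied to the
#' pipeline instead.
#'
#' @param a,b Unaligned amino-acid strings.
#' @return Named character vector of two aligned strings.
#' @export
align_protein_pair <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  c(as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)))
}

#' Ks distribution for one taxon from a self-hit report
#'
#' Filters the within-taxon hit report ([filter_self_hits()]), and for
#' each retained paralog pair aligns the peptides (built-in aligner or
#' supplied alignments), back-translates to codons against the CDS,
#' and computes NG86 distances ([ng86()]).
#'
#' @param hits Within-taxon hit report data.frame.
#' @param pep Named character vector of peptide sequences.
#' @param cds Named character vector of CDS sequences.
#' @param taxon Taxon code for the output.
#' @param alignments Optional named list `"id1|id2"` -> two-row protein
#'   alignment; pairs without an entry use [align_protein_pair()].
#' @param min_pident,min_nident,max_hits See [filter_self_hits()].
#' @param bin_width,range See [ks_histogram()].
#' @return List with `pairs` (data.frame `id1`, `id2`, `ka`, `ks`,
#'   `saturated`), and `histogram` (a `ks_distribution`).
#' @export
ks_pipeline <- function(hits, pep, cds, taxon = NA_character_,
                        alignments = NULL, min_pident = 20,
                        min_nident = 50, max_hits = 10,
                        bin_width = 0.05, range = c(0, 2)) {
  pairs <- filter_self_hits(hits, min_pident, min_nident, max_hits)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    i1 <- pairs$id1[i]; i2 <- pairs$id2[i]
    key <- paste(i1, i2, sep = "|")
    aln <- if (!is.null(alignments) && key %in% names(alignments))
      alignments[[key]]
    else setNames(align_protein_pair(pep[[i1]], pep[[i2]]), c(i1, i2))
    codon <- back_translate(aln, cds)
    k <- ng86(codon)
    data.frame(id1 = i1, id2 = i2, ka = k$ka, ks = k$ks,
               saturated = k$saturated_ks, stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(id1 = character(), id2 = character(), ka = numeric(),
               ks = numeric(), saturated = logical(),
               stringsAsFactors = FALSE)
  list(pairs = out,
       histogram = ks_histogram(out$ks, bin_width, range, taxon))
}
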