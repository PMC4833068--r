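# independent per-codon oracle for NG86 synonymous site counts, written
# against its own genetic-code table (seqinr), not the package internals
oracle_syn_sites <- function(codons) {
  nts <- c("a", "c", "g", "t")
  total <- 0
  for (cd in tolower(codons)) {
    aa <- seqinr::translate(strsplit(cd, "")[[1]])
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(cd, pos, pos))) {
        alt <- cd
        substr(alt, pos, pos) <- nt
        alt_aa <- seqinr::translate(strsplit(alt, "")[[1]])
        if (alt_aa != "*" && alt_aa == aa) total <- total + 1 / 3
      }
    }
  }
  total
}

codon_split <- function(s) {
  n <- nchar(s)
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

pair_aln <- function(s1, s2) {
  rbind(a = strsplit(s1, "")[[1]], b = strsplit(s2, "")[[1]])
}

test_that("identical sequences have zero distances", {
  s <- "ATGAAACCCGGG"
  k <- ng86(pair_aln(s, s))
  expect_equal(k$ks, 0)
  expect_equal(k$ka, 0)
  expect_false(k$saturated_ks)
})

test_that("third-position synonymous changes give the exact NG86 value", {
  # 100 codons, 6 synonymous third-position changes; S from the oracle
  set.seed(61)
  fourfold <- c("GGT", "GCT", "GTT", "CCT", "ACT", "TCT", "CGT", "CTT")
  codons <- sample(fourfold, 100, replace = TRUE)
  mutated <- codons
  change <- sample(100, 6)
  for (i in change) {
    base <- substr(mutated[i], 3, 3)
    substr(mutated[i], 3, 3) <- sample(setdiff(c("A", "C", "G", "T"),
                                               base), 1)
  }
  s1 <- paste(codons, collapse = ""); s2 <- paste(mutated, collapse = "")
  S <- (oracle_syn_sites(codons) + oracle_syn_sites(mutated)) / 2
  k <- ng86(pair_aln(s1, s2))
  expect_equal(k$S, S)
  expect_equal(k$sd, 6)
  expect_equal(k$ks, -3 / 4 * log(1 - 4 / 3 * (6 / S)))
  expect_equal(k$ka, 0)
})

test_that("ng86 is symmetric and handles degeneracies", {
  p <- sim_paralog_pair(150, 0.4, 0.05, seed = 8)
  k1 <- ng86(pair_aln(p$cds1, p$cds2))
  k2 <- ng86(pair_aln(p$cds2, p$cds1))
  expect_equal(k1$ks, k2$ks)
  expect_equal(k1$ka, k2$ka)
  # gapped/ambiguous codons are dropped before counting
  s1 <- "ATGAAA---CCC"; s2 <- "ATGAAGNNNCCC"
  k <- ng86(pair_aln(s1, s2))
  expect_equal(k$n_codons, 3L)
  # internal stop codon is an error
  expect_error(ng86(pair_aln("ATGTAAAAA", "ATGTAAAAA")), "stop codon")
  expect_error(ng86(pair_aln("ATGC", "ATGA")), "divisible")
})

test_that("ks is non-decreasing under added synonymous differences", {
  set.seed(17)
  fourfold <- c("GGT", "GCT", "GTT", "CCT", "ACT", "TCT")
  codons <- sample(fourfold, 80, replace = TRUE)
  mutated <- codons
  prev <- 0
  order <- sample(80)
  for (step in 1:12) {
    i <- order[step]
    base <- substr(mutated[i], 3, 3)
    substr(mutated[i], 3, 3) <- sample(setdiff(c("A", "C", "G", "T"),
                                               base), 1)
    k <- ng86(pair_aln(paste(codons, collapse = ""),
                       paste(mutated, collapse = "")))
    expect_gte(k$ks, prev)
    prev <- k$ks
  }
})

test_that("saturation is flagged at pS >= 3/4", {
  # every fourfold third position differs: ps = sd/S reaches 1
  k <- ng86(pair_aln("GGAGGAGGAGGA", "GGTGGCGGGGGT"))
  expect_gte(k$ps, 0.75)
  expect_true(k$saturated_ks)
  expect_true(is.na(k$ks))
  expect_false(k$saturated_ka)
})

test_that("self-hit filtering applies boundaries and the hit-count rule", {
  hits <- data.frame(
    query = c("a", "a", "b", "c", "d", "d"),
    subject = c("b", "b", "a", "d", "c", "e"),
    pident = c(50, 50, 50, 19.5, 50, 49),
    nident = c(100, 100, 100, 100, 100, 49),
    stringsAsFactors = FALSE)
  out <- filter_self_hits(hits)
  # a-b deduplicated (kept once), c-d dropped on pident (19.5 < 20),
  # d-c kept (50/100), d-e dropped on nident (49 < 50)
  expect_equal(nrow(out), 2L)
  expect_setequal(paste(out$id1, out$id2), c("a b", "c d"))
  # boundary: nident exactly 50 kept
  h2 <- data.frame(query = "x", subject = "y", pident = 20, nident = 50)
  expect_equal(nrow(filter_self_hits(h2)), 1L)
  h3 <- data.frame(query = "x", subject = "y", pident = 20, nident = 49)
  expect_equal(nrow(filter_self_hits(h3)), 0L)
  # a sequence reaching max_hits is removed with all its pairs
  many <- data.frame(query = "hub", subject = paste0("s", 1:10),
                     pident = 60, nident = 100)
  lone <- data.frame(query = "s1", subject = "s2", pident = 60,
                     nident = 100)
  out <- filter_self_hits(rbind(many, lone), max_hits = 10)
  expect_false("hub" %in% c(out$id1, out$id2))
  expect_equal(nrow(out), 1L)
  # idempotent
  out_df <- filter_self_hits(rbind(many, lone))
  again <- filter_self_hits(data.frame(query = out_df$id1,
                                       subject = out_df$id2,
                                       pident = out_df$pident,
                                       nident = out_df$nident))
  expect_equal(nrow(again), nrow(out_df))
})

test_that("histograms use fixed edges with an overflow bucket", {
  h <- ks_histogram(c(0.12, 0.13), bin_width = 0.05, range = c(0, 2))
  bin <- which(h$breaks == 0.10)
  expect_equal(h$counts[bin], 2L)
  expect_equal(sum(h$counts), 2L)
  h0 <- ks_histogram(numeric(0))
  expect_equal(sum(h0$counts), 0L)
  h2 <- ks_histogram(c(0.5, 2.5, NA))
  expect_equal(sum(h2$counts), 1L)
  expect_equal(h2$overflow, 2L)
})

test_that("simulated WGD pairs put the modal Ks bin near the target", {
  ks <- vapply(1:60, function(i) {
    noisy <- 0.6 * exp(stats::rnorm(1, 0, 0.08))
    p <- sim_paralog_pair(300, noisy, 0, seed = 1000 + i)
    ng86(pair_aln(p$cds1, p$cds2))$ks
  }, numeric(1))
  h <- ks_histogram(ks)
  modal <- which.max(h$counts)
  mid <- (h$breaks[modal] + h$breaks[modal + 1]) / 2
  expect_gte(mid, 0.5)
  expect_lte(mid, 0.7)
})

test_that("the ks pipeline runs end to end on constructed paralogs", {
  pairs <- lapply(1:4, function(i) sim_paralog_pair(120, 0.3, 0.05,
                                                    seed = 40 + i))
  pep <- c(); cds <- c(); rows <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    i1 <- sprintf("T@p%da", i); i2 <- sprintf("T@p%db", i)
    code <- Biostrings::GENETIC_CODE
    pep1 <- paste(code[codon_split(p$cds1)], collapse = "")
    pep2 <- paste(code[codon_split(p$cds2)], collapse = "")
    pep[i1] <- pep1; pep[i2] <- pep2
    cds[i1] <- p$cds1; cds[i2] <- p$cds2
    rows[[i]] <- data.frame(query = i1, subject = i2, pident = 95,
                            nident = 110, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  res <- ks_pipeline(hits, pep, cds, taxon = "T")
  expect_equal(nrow(res$pairs), 4L)
  expect_true(all(res$pairs$ks > 0.15 & res$pairs$ks < 0.5))
  expect_s3_class(res$histogram, "ks_distribution")
})
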