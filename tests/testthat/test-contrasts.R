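test_that("back-translation maps residues to source codons", {
  out <- back_translate(c(s1 = "M-K"), c(s1 = "ATGAAA"))
  expect_equal(paste(out["s1", ], collapse = ""), "ATG---AAA")
  # terminal stop on the CDS is tolerated and dropped
  out <- back_translate(c(s1 = "MK"), c(s1 = "ATGAAATAA"))
  expect_equal(paste(out["s1", ], collapse = ""), "ATGAAA")
  # codon disagreeing with the residue is an error naming the position
  expect_error(back_translate(c(s1 = "MK"), c(s1 = "ATGGGG")),
               "residue 2")
  expect_error(back_translate(c(s1 = "MK"), c(s1 = "ATGAAAAA")),
               "length mismatch")
  expect_error(back_translate(c(s1 = "MK"), c(other = "ATGAAA")),
               "CDS missing")
})

test_that("codon-column trimming is boundary inclusive at 20%", {
  # 10 rows; first codon column has 1 unambiguous codon (0.1 < 0.2),
  # second has 2 (0.2, kept), third all unambiguous
  rows <- lapply(1:10, function(i) {
    c1 <- if (i == 1) c("A", "T", "G") else c("-", "-", "-")
    c2 <- if (i <= 2) c("A", "A", "A") else c("N", "N", "N")
    c(c1, c2, c("G", "G", "G"))
  })
  aln <- do.call(rbind, rows)
  rownames(aln) <- paste0("s", 1:10)
  out <- trim_codon_columns(aln, 0.2)
  expect_equal(ncol(out), 6L)
  expect_equal(out[1, 1:3], c("A", "A", "A"))
  # fully unambiguous alignment is unchanged
  full <- matrix(rep(c("A", "T", "G"), 4), nrow = 2, byrow = TRUE)
  rownames(full) <- c("a", "b")
  expect_identical(trim_codon_columns(full, 0.2), full)
  expect_error(trim_codon_columns(full[, 1:4], 0.2), "divisible by 3")
})

test_that("stepwise averaging is the cherry-weighted recursion", {
  tr <- read_newick(text = "(A:0.1,B:0.3);")
  expect_equal(stepwise_average(tr, 3), 0.2)
  tr <- read_newick(text = "((A:0.1,B:0.1):0.1,C:0.3);")
  root <- 4
  expect_equal(stepwise_average(tr, root), 0.25)  # not tip-average 0.2333
  expect_equal(stepwise_average(tr, 1), 0)  # single tip
  # ladder with one tip per level equals the path length
  lad <- read_newick(text = "(((A:0.1):0.2):0.3);")
  # agreement with an independent recursion oracle on random trees
  set.seed(3)
  for (rep in 1:40) {
    tr <- random_tree(sample(3:12, 1))
    node <- sample(length(tr$tip.label) + seq_len(tr$Nnode), 1)
    expect_equal(stepwise_average(tr, node), oracle_stepwise(tr, node))
  }
})

test_that("contrasts are signed, antisymmetric, and window-excluded", {
  nwk <- "((W1@a:0.1,W2@a:0.1):0.05,(H1@a:0.3,H2@a:0.3):0.05);"
  tr <- read_newick(text = nwk)
  tm <- letter_tm(c("W1", "W2", "H1", "H2"),
                  habit = c(W1 = "W", W2 = "W", H1 = "H", H2 = "H"))
  root <- 5
  wch <- mrca_node(tr, c("W1@a", "W2@a"))
  hch <- mrca_node(tr, c("H1@a", "H2@a"))
  rt <- rate_trees(tr, tr$edge.length, tr$edge.length)
  ct <- compute_contrast(rt, root, wch, hch)
  # L_W = 0.05 + 0.1 = 0.15, L_H = 0.05 + 0.3 = 0.35
  expect_equal(ct$ds_contrast, (0.35 - 0.15) / 0.15)
  expect_true(ct$ds_included)
  expect_equal(ct$woody_tips, 2L)
  # swapping the labels flips the sign, magnitude unchanged
  ct_sw <- compute_contrast(rt, root, hch, wch)
  expect_equal(ct_sw$ds_contrast, -ct$ds_contrast)
  # simple arithmetic: 0.1 vs 0.3 gives +/-2
  tr2 <- read_newick(text = "(W1@a:0.1,H1@a:0.3);")
  rt2 <- rate_trees(tr2, tr2$edge.length, tr2$edge.length)
  ct2 <- compute_contrast(rt2, 3, 1, 2, include_stem = TRUE)
  expect_equal(ct2$ds_contrast, 2)
  ct2r <- compute_contrast(rt2, 3, 2, 1)
  expect_equal(ct2r$ds_contrast, -2)  # herbaceous child now the short one
  # |contrast| > 10 is excluded
  tr3 <- read_newick(text = "(W1@a:0.01,H1@a:0.25);")
  rt3 <- rate_trees(tr3, tr3$edge.length, tr3$edge.length)
  ct3 <- compute_contrast(rt3, 3, 1, 2)
  expect_equal(ct3$ds_contrast, 24)
  expect_false(ct3$ds_included)
  # zero shorter side is excluded rather than infinite
  tr4 <- read_newick(text = "(W1@a:0,H1@a:0.2);")
  rt4 <- rate_trees(tr4, tr4$edge.length, tr4$edge.length)
  expect_false(compute_contrast(rt4, 3, 1, 2)$ds_included)
})

test_that("the sign test is the exact symmetric binomial test", {
  expect_equal(sign_test(3, 3), 1)
  expect_equal(signif(sign_test(66, 180), 2), 2.1e-13)
  expect_equal(signif(sign_test(84, 162), 2), 7.5e-7)
  # cross-check against stats::binom.test and exhaustive enumeration
  for (n in 1:25) {
    for (k in 0:n) {
      mine <- sign_test(k, n - k)
      ref <- stats::binom.test(k, n, 0.5)$p.value
      expect_equal(mine, ref, tolerance = 1e-12)
      # enumeration of the binomial pmf: sum of outcomes at most as likely
      pmf <- stats::dbinom(0:n, n, 0.5)
      enum <- sum(pmf[pmf <= stats::dbinom(k, n, 0.5) + 1e-12])
      expect_equal(mine, min(1, enum), tolerance = 1e-9)
    }
  }
  expect_warning(p <- sign_test(0, 0), "undefined")
  expect_true(is.na(p))
})

test_that("branch-model labeling marks the sister clades", {
  tm <- letter_tm(c("W1", "W2", "H1", "H2", "B1"),
                  habit = c(W1 = "W", W2 = "W", H1 = "H", H2 = "H"))
  defn <- contrast_definition("A", c("W1", "W2"), c("H1", "H2"), tm)
  tr <- read_newick(text = paste0(
    "(((W1@a:1,W2@a:1):1,(H1@a:1,H2@a:1):1):1,B1@a:1);"))
  cands <- label_branch_model(tr, defn, tm)
  expect_equal(length(cands), 1L)
  expect_match(cands[[1]]$labeled_newick, "#1")
  expect_match(cands[[1]]$labeled_newick, "#2")
  expect_equal(cands[[1]]$config$model, 2)
  expect_equal(cands[[1]]$woody_tips, 2L)
  # clade with no herbaceous taxa: skipped with a reason
  tr2 <- read_newick(text = "((W1@a:1,W2@a:1):1,B1@a:1);")
  out <- label_branch_model(tr2, defn, tm)
  expect_equal(length(out), 0L)
  expect_match(attr(out, "reason"), "no woody/herbaceous")
  # multiple candidate pairs are all emitted
  tr3 <- read_newick(text = paste0(
    "(((W1@a:1,H1@a:1):1,(W2@a:1,H2@a:1):1):1,B1@a:1);"))
  expect_equal(length(label_branch_model(tr3, defn, tm)), 2L)
})

test_that("contrast definitions validate habits and read from TSV", {
  tm <- letter_tm(c("W1", "H1"), habit = c(W1 = "W", H1 = "H"))
  expect_error(contrast_definition("A", "H1", "W1", tm), "woody")
  f <- tempfile()
  writeLines(c("label\tside\ttaxon", "A\tW\tW1", "A\tH\tH1"), f)
  defs <- read_contrast_definitions(f, tm)
  expect_equal(defs$A$woody, "W1")
})

test_that("rate-tree pairs align dN lengths onto the dS topology", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines("((A:0.1,B:0.2):0.3,C:0.4);", f1)
  writeLines("((B:2,A:1):3,C:4);", f2)  # same topology, rotated
  rt <- read_rate_trees(f1, f2)
  i_a <- match(match("A", rt$topology$tip.label), rt$topology$edge[, 2])
  expect_equal(rt$dn[i_a], 1)
  writeLines("((A:1,C:2):3,B:4);", f2)
  expect_error(read_rate_trees(f1, f2), "different topologies")
})

test_that("the study driver recovers a strong herbaceous rate excess", {
  cfg <- sim_config(n_families = 60, dup_rate = 0.02, loss_rate = 0.01,
                    isoform_rate = 0, contaminant_rate = 0, seed = 29)
  tm <- cfg$species$tm
  clades <- list()
  for (i in seq_len(cfg$n_families)) {
    h <- simulate_homolog_tree(cfg, i)
    if (is.null(h$rates)) next
    clades <- c(clades, extract_rate_clades(h$rates, tm))
  }
  study <- run_contrast_study(clades, cfg$species$contrasts, tm,
                              n_sub = 3000, seed = 5)
  tab <- study$table_all
  expect_true(all(tab$p < 1e-4))
  expect_true(all(tab$median_contrast > 0))
  # equal-tip-count control shows the same direction
  eq <- study$table_equal_tips
  expect_true(all(eq$median_contrast > 0))
  # fewer pairs available than n_sub: all used, reproducibly
  study2 <- run_contrast_study(clades, cfg$species$contrasts, tm,
                               n_sub = 3000, seed = 99)
  expect_equal(study2$table_all$n_pairs, tab$n_pairs)
})
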