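test_that("hit filtering applies identity, coverage, and E-value rules", {
  hits <- data.frame(
    query = c("q1", "q2", "q3", "q4", "q5"),
    subject = c("s1", "s2", "s3", "s4", "q5"),
    pident = c(60, 40, 60, 60, 99),
    evalue = c(1e-10, 1e-10, 1e-10, 1e-3, 1e-50),
    qcov = c(0.8, 0.9, 0.5, 0.8, 1.0),
    stringsAsFactors = FALSE)
  kept <- filter_hits(hits, curation_params())
  expect_equal(kept$query, "q1")  # q2 identity, q3 coverage, q4 evalue,
                                  # q5 self-hit
})

test_that("hit tables parse tabular reports and flag malformed rows", {
  f <- tempfile()
  writeLines(c(
    "q1\ts1\t90.0\t100\t10\t0\t1\t100\t1\t100\t1e-50\t200\t120\t130",
    "q2\ts2\t80.0\t50\t10\t0\t11\t60\t1\t50\t1e-20\t90\t100\t80"), f)
  df <- read_hit_table(f)
  expect_equal(df$nident, c(90L, 40L))
  expect_equal(df$qcov, c(100 / 120, 50 / 100))
  writeLines("q1\ts1\tbroken", f)
  expect_error(read_hit_table(f), "line 1")
})

test_that("cluster filter drops short sequences and small clusters", {
  tm <- letter_tm(LETTERS[1:10])
  members <- setNames(rep(strrep("M", 50), 9), paste0(LETTERS[1:9], "@1"))
  g <- homolog_group("g1", members)

  short <- g
  short$members[1] <- strrep("M", 39)
  out <- filter_cluster(short, curation_params(), tm)
  expect_false("A@1" %in% names(out$members))
  expect_equal(length(out$members), 8L)

  seven <- homolog_group("g2", members[1:7])
  expect_true(is_rejected(filter_cluster(seven, curation_params(), tm)))

  eight <- homolog_group("g3", members[1:8])
  out <- filter_cluster(eight, curation_params(), tm)
  expect_equal(length(out$members), 8L)
})

test_that("column trimming follows the occupancy boundary exactly", {
  # 100 rows: a column with 4 non-gap cells (0.04) is removed at 0.05,
  # one with 6 (0.06) is kept
  col_of <- function(k) c(rep("M", k), rep("-", 100 - k))
  aln <- cbind(col_of(4), col_of(6), col_of(100))
  rownames(aln) <- paste0("s", 1:100, "@1")
  out <- trim_columns(aln, 0.05)
  expect_equal(ncol(out), 2L)
  expect_equal(out[1, ], c("M", "M"))
  # threshold 0 keeps everything
  expect_equal(ncol(trim_columns(aln, 0)), 3L)
  expect_error(trim_columns(aln[0, , drop = FALSE], 0.05), "empty")
})

test_that("column trimming never edits residues and reports all-gap rows", {
  set.seed(5)
  chars <- c("A", "C", "D", "-", "-")
  aln <- matrix(sample(chars, 20 * 30, TRUE), nrow = 20)
  rownames(aln) <- paste0("s", 1:20, "@1")
  out <- trim_columns(aln, 0.5)
  before <- sum(!(aln %in% c("-", "X", "*", "?", ".")))
  after <- sum(!(out %in% c("-", "X", "*", "?", ".")))
  expect_lte(after, before)
  # kept columns are verbatim copies
  keep_cols <- which(colMeans(matrix(!(aln %in% c("-", "X", "*", "?", ".")),
                                     nrow(aln))) >= 0.5)
  expect_identical(out[, seq_along(keep_cols)],
                   aln[, keep_cols, drop = FALSE])
  aln2 <- rbind(aln, allgap = rep("-", 30))
  rownames(aln2)[21] <- "gap@1"
  out2 <- trim_columns(aln2, 0.5)
  expect_true("gap@1" %in% attr(out2, "allgap_rows"))
  expect_true("gap@1" %in% rownames(out2))
})

test_that("long-branch cutting separates components at the cutoff", {
  tr <- read_newick(text = "((A:0.1,B:0.1):2.5,(C:0.1,D:0.1):0.1);")
  comps <- cut_long_branches(tr, 2)
  sets <- lapply(comps, function(x) sort(x$tip.label))
  expect_equal(length(comps), 2L)
  expect_true(list(c("A", "B")) %in% sets && list(c("C", "D")) %in% sets)
  for (cc in comps) expect_true(all(cc$edge.length <= 2))

  # all branches below the cutoff: one identical component
  ok <- read_newick(text = "((A:0.1,B:0.1):0.5,(C:0.1,D:0.1):0.1);")
  one <- cut_long_branches(ok, 2)
  expect_equal(length(one), 1L)
  expect_equal(sort(one[[1]]$tip.label), c("A", "B", "C", "D"))

  # two disjoint long branches give three components
  tr3 <- read_newick(
    text = "((A:3,B:0.1):0.1,((C:0.1,D:0.1):3,(E:0.1,F:0.1):0.1):0.1);")
  comps3 <- cut_long_branches(tr3, 2)
  expect_equal(length(comps3), 3L)
  expect_setequal(vapply(comps3, function(x)
    paste(sort(x$tip.label), collapse = "+"), character(1)),
    c("A", "C+D", "B+E+F"))
})

test_that("branch cutting is invariant to re-rooting", {
  set.seed(11)
  tr <- random_tree(14, mean_len = 0.4)
  tr$edge.length[sample(nrow(tr$edge), 3)] <- 2.5
  ref <- sort(vapply(cut_long_branches(tr, 2), function(x)
    paste(sort(x$tip.label), collapse = "+"), character(1)))
  for (rep in 1:50) {
    tip <- sample(tr$tip.label, 1)
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    got <- sort(vapply(cut_long_branches(rr, 2), function(x)
      paste(sort(x$tip.label), collapse = "+"), character(1)))
    expect_equal(got, ref)
  }
})

test_that("spurious-tip removal needs both the absolute and ratio rules", {
  # tip 0.25 vs sister tip 0.01: removed
  tr <- read_newick(text = "((A:0.25,B:0.01):0.1,C:0.1);")
  out <- remove_spurious_tips(tr)
  expect_false("A" %in% out$tip.label)
  # ratio only 5: kept
  tr <- read_newick(text = "((A:0.25,B:0.05):0.1,C:0.1);")
  expect_true("A" %in% remove_spurious_tips(tr)$tip.label)
  # below the absolute cutoff: kept
  tr <- read_newick(text = "((A:0.15,B:0.001):0.1,C:0.1);")
  expect_true("A" %in% remove_spurious_tips(tr)$tip.label)
  # subtree sister measured by stem + stepwise depth
  tr <- read_newick(text = "((A:0.5,(B:0.01,C:0.01):0.01):0.1,D:0.1);")
  out <- remove_spurious_tips(tr)
  expect_false("A" %in% out$tip.label)
  # unary suppression merges lengths additively
  b_node <- match("B", out$tip.label)
  expect_equal(sort(out$tip.label), c("B", "C", "D"))
})

test_that("isoform masking keeps the best-covered tip of each group", {
  tm <- letter_tm(c("X", "Y", "Z"))
  # monophyletic cherry
  tr <- read_newick(text = "((X@1:0.01,X@2:0.01):0.1,Y@1:0.1);")
  out <- mask_isoform_tips(tr, tm, c("X@1" = 300, "X@2" = 200, "Y@1" = 100))
  expect_setequal(out$tip.label, c("X@1", "Y@1"))
  # paraphyletic grade: keep the best of the three X isoforms
  tr <- read_newick(
    text = "(X@1:0.1,(X@2:0.1,(X@3:0.1,Y@1:0.1):0.1):0.1);")
  out <- mask_isoform_tips(tr, tm,
                           c("X@1" = 10, "X@2" = 50, "X@3" = 20, "Y@1" = 5))
  expect_setequal(out$tip.label, c("X@2", "Y@1"))
  # one tip per taxon: unchanged
  tr <- read_newick(text = "((X@1:0.1,Y@1:0.1):0.1,Z@1:0.1);")
  out <- mask_isoform_tips(tr, tm, c("X@1" = 1, "Y@1" = 1, "Z@1" = 1))
  expect_setequal(out$tip.label, c("X@1", "Y@1", "Z@1"))
  # ties break to the lexicographically smallest id
  tr <- read_newick(text = "((X@b:0.01,X@a:0.01):0.1,Y@1:0.1);")
  out <- mask_isoform_tips(tr, tm, c("X@a" = 7, "X@b" = 7, "Y@1" = 1))
  expect_true("X@a" %in% out$tip.label)
  expect_error(mask_isoform_tips(tr, tm, c("X@a" = 7)), "X@b")
})

test_that("masking leaves at most one tip per injected isoform group", {
  cfg <- sim_config(n_families = 40, isoform_rate = 0.3,
                    contaminant_rate = 0, seed = 31)
  tm <- cfg$species$tm
  n_with_iso <- 0
  for (i in seq_len(cfg$n_families)) {
    h <- simulate_homolog_tree(cfg, i)
    if (is.null(h$tree) || length(h$truth$isoforms) == 0) next
    n_with_iso <- n_with_iso + 1
    cc <- setNames(sample(100:200, length(h$tree$tip.label), TRUE),
                   h$tree$tip.label)
    out <- mask_isoform_tips(h$tree, tm, cc)
    # no injected isoform pair survives intact: an isoform tip and its
    # base tip are never both present
    for (iso in h$truth$isoforms) {
      base <- sub("iso$", "", iso)
      expect_false(all(c(iso, base) %in% out$tip.label))
    }
  }
  expect_gt(n_with_iso, 5)
})

test_that("curation pipeline is the identity on artifact-free input", {
  # equal rates and low noise so no branch honestly crosses a cutoff
  cfg <- sim_config(n_families = 6, dup_rate = 0.05, loss_rate = 0.02,
                    herb_multiplier_ds = 1, herb_multiplier_dn = 1,
                    rate_sdlog = 0.1,
                    isoform_rate = 0, contaminant_rate = 0, seed = 13)
  tm <- cfg$species$tm
  for (i in 1:6) {
    h <- simulate_homolog_tree(cfg, i)
    if (is.null(h$tree)) next
    if (max(h$tree$edge.length) > 0.5) next  # honest long branch, skip
    # same-taxon tips from real duplications are masked by design; the
    # identity property concerns families without them
    if (anyDuplicated(seq_taxon(h$tree$tip.label))) next
    g <- uniform_group(paste0("fam", i), h$tree)
    out <- curate_pipeline(g, curation_params(), tm)
    expect_equal(length(out), 1L)
    expect_setequal(out[[1]]$tree$tip.label, h$tree$tip.label)
    lg <- attr(out, "removal_log")
    expect_equal(nrow(lg[lg$stage %in% c("spurious_tip", "isoform_mask"), ]),
                 0L)
  }
})

test_that("curation pipeline separates contaminants and masks isoforms", {
  cfg <- sim_config(n_families = 30, dup_rate = 0.05, loss_rate = 0.02,
                    isoform_rate = 0.15, contaminant_rate = 1, seed = 17)
  tm <- cfg$species$tm
  n_checked <- 0
  for (i in seq_len(cfg$n_families)) {
    h <- simulate_homolog_tree(cfg, i)
    if (is.null(h$tree) || length(h$truth$contaminants) == 0) next
    g <- uniform_group(paste0("fam", i), h$tree)
    out <- curate_pipeline(g, curation_params(), tm)
    for (og in out) {
      # the contaminant tip (+3 subs/site terminal branch) never
      # survives inside a curated group with other tips
      if (length(og$tree$tip.label) > 1)
        expect_false(any(h$truth$contaminants %in% og$tree$tip.label))
      # no isoform pair survives
      for (iso in h$truth$isoforms) {
        base <- sub("iso$", "", iso)
        expect_false(all(c(iso, base) %in% og$tree$tip.label))
      }
    }
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)
})
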