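# Gene-family simulator: birth-death duplication/loss along a species
# tree, episodic whole-genome duplications with copy retention,
# habit-linked branch-rate multipliers, assembly isoforms, contaminant
# long branches, and codon-pair generation at a target Ks. Provides the
# ground truth against which every pipeline stage is tested.

#' Example species tree and taxon map for simulations
#'
#' A fixed 16-taxon design: 12 ingroup taxa forming three
#' woody/herbaceous sister-pair comparisons (A: 3 woody vs 3 herbaceous;
#' B: 2 vs 2; C: 1 vs 1), three outgroup taxa, and a single deeper
#' outgroup taxon (`Aqu`) used for rooting homolog trees. Branch lengths
#' are in time units.
#'
#' @return List with `tree` (rooted `phylo`), `tm` (a [taxon_map()] with
#'   habits, an `"ingroup"` clade set, and root taxon `Aqu`), and
#'   `contrasts` (list of three [contrast_definition()]s).
#' @export
example_species_tree <- function() {
  nwk <- paste0(
    "(((((((wA1:0.2,(wA2:0.1,wA3:0.1):0.1):0.1,",
    "(hA1:0.2,(hA2:0.1,hA3:0.1):0.1):0.1):0.2,",
    "((wB1:0.15,wB2:0.15):0.15,(hB1:0.15,hB2:0.15):0.15):0.2):0.15,",
    "(wC1:0.3,hC1:0.3):0.2):0.25,Out1:1.0):0.15,",
    "(Out2:0.8,Out3:0.8):0.35):0.15,Aqu:1.3);")
  tree <- read_newick(text = nwk)
  ingroup <- c("wA1", "wA2", "wA3", "hA1", "hA2", "hA3",
               "wB1", "wB2", "hB1", "hB2", "wC1", "hC1")
  taxa <- c(ingroup, "Out1", "Out2", "Out3", "Aqu")
  habit <- setNames(ifelse(startsWith(ingroup, "w"), "W", "H"), ingroup)
  tm <- taxon_map(taxa, ingroup = ingroup, habit = habit,
                  clades = list(ingroup = ingroup),
                  root_taxon = "Aqu", delimiter = "@")
  contrasts <- list(
    contrast_definition("A", c("wA1", "wA2", "wA3"),
                        c("hA1", "hA2", "hA3"), tm),
    contrast_definition("B", c("wB1", "wB2"), c("hB1", "hB2"), tm),
    contrast_definition("C", "wC1", "hC1", tm))
  list(tree = tree, tm = tm, contrasts = contrasts)
}

#' Simulation configuration
#'
#' Defines the data-generating conditions: gene lineages evolve along the
#' species tree under birth-death duplication/loss; whole-genome
#' duplications act instantaneously at the start of their branch, each
#' surviving lineage gaining a second retained copy with the stated
#' probability; dS and dN branch lengths are the time lengths scaled by a
#' base rate, multiplied on all-herbaceous branches by the habit
#' multiplier, with lognormal noise. Defaults emulate the conditions the
#' toolkit targets: a 3x herbaceous rate multiplier on both dS and dN, a
#' single WGD with 30% copy retention on the branch subtending the
#' contrast-A clade, a low background duplication rate, occasional
#' assembly isoforms and spuriously long contaminant branches.
#'
#' @param species A list as from [example_species_tree()] (fields `tree`,
#'   `tm`).
#' @param n_families Number of gene families.
#' @param dup_rate,loss_rate Birth-death rates per lineage per unit branch
#'   length.
#' @param wgd_events List of `list(taxa = <taxa defining the branch via
#'   their MRCA>, retention = <probability>)`; `NULL` for none.
#' @param herb_multiplier_ds,herb_multiplier_dn Rate multipliers applied
#'   to branches whose descendant tips are all herbaceous.
#' @param base_ds,base_dn Substitutions/site per unit time on woody
#'   (background) branches.
#' @param rate_sdlog Lognormal noise (sdlog) on per-branch rates.
#' @param isoform_rate Per-tip probability of an injected near-identical
#'   isoform sister tip.
#' @param contaminant_rate Per-family probability of one spuriously long
#'   terminal branch (+3 substitutions/site).
#' @param support_range Range of synthetic bootstrap supports drawn for
#'   internal nodes.
#' @param seed Master seed recorded in all outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(species = example_species_tree(),
                       n_families = 100,
                       dup_rate = 0.1, loss_rate = 0.05,
                       wgd_events = list(list(
                         taxa = c("wA1", "wA2", "wA3",
                                  "hA1", "hA2", "hA3"),
                         retention = 0.3)),
                       herb_multiplier_ds = 3, herb_multiplier_dn = 3,
                       base_ds = 0.3, base_dn = 0.1,
                       rate_sdlog = 0.3,
                       isoform_rate = 0.05, contaminant_rate = 0.02,
                       support_range = c(90, 100),
                       seed = 1) {
  stopifnot(dup_rate >= 0, loss_rate >= 0, isoform_rate >= 0,
            contaminant_rate >= 0)
  wgd_nodes <- integer(0)
  wgd_ret <- numeric(0)
  for (ev in wgd_events) {
    stopifnot(ev$retention >= 0, ev$retention <= 1)
    wgd_nodes <- c(wgd_nodes, mrca_node(species$tree, ev$taxa))
    wgd_ret <- c(wgd_ret, ev$retention)
  }
  structure(list(species = species, n_families = n_families,
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 wgd_nodes = wgd_nodes, wgd_retention = wgd_ret,
                 herb_multiplier_ds = herb_multiplier_ds,
                 herb_multiplier_dn = herb_multiplier_dn,
                 base_ds = base_ds, base_dn = base_dn,
                 rate_sdlog = rate_sdlog,
                 isoform_rate = isoform_rate,
                 contaminant_rate = contaminant_rate,
                 support_range = support_range, seed = seed),
            class = "sim_config")
}

#' Simulate one gene family along the species tree
#'
#' A single gene lineage enters at the species root and evolves by
#' lineage-wise Gillespie birth-death along every species branch; at a
#' WGD branch each surviving lineage gains a retained second copy with
#' the configured probability. The returned time tree is congruent with
#' the species tree when rates are zero and no WGD applies. The truth
#' record lists every duplication with its species branch (identified by
#' the species node below the branch).
#'
#' @param config A [sim_config()].
#' @param family_index Family number (used for tip labels and the
#'   family's sub-seed, so families are independently reproducible).
#' @return List with `time_tree` (`phylo`, branch lengths in time units;
#'   `NULL` when the family went extinct or has a single tip), `truth`
#'   (list with `dups` data.frame of `species_node`, `type`
#'   (`"bd"`/`"wgd"`)), and `family` (the index).
#' @export
simulate_family <- function(config, family_index) {
  seed <- .sub_seeds(config$seed, family_index)[family_index]
  .with_seed(seed, .simulate_family_impl(config, family_index))
}

#' @noRd
.simulate_family_impl <- function(config, family_index) {
  sp <- config$species$tree
  ntip <- length(sp$tip.label)
  kids <- .children_list(sp)
  lam <- config$dup_rate; mu <- config$loss_rate
  dups <- list()
  counters <- new.env(parent = emptyenv())
  tip_label <- function(taxon) {
    k <- (if (is.null(counters[[taxon]])) 0L else counters[[taxon]]) + 1L
    counters[[taxon]] <- k
    paste0(taxon, "@g", family_index, "c", k)
  }
  # fragment: list(tip = label or NULL, len, children = list of fragments)
  frag_tip <- function(label, len = 0) list(tip = label, len = len,
                                            children = NULL)
  frag_node <- function(children, len = 0) list(tip = NULL, len = len,
                                                children = children)
  add_len <- function(fr, dt) { fr$len <- fr$len + dt; fr }
  # one lineage evolving over the remainder of species branch to node v
  evolve <- function(t_rem, v, continue) {
    if (lam + mu <= 0) {
      fr <- continue()
      return(if (is.null(fr)) NULL else add_len(fr, t_rem))
    }
    t_ev <- stats::rexp(1L, lam + mu)
    if (t_ev >= t_rem) {
      fr <- continue()
      return(if (is.null(fr)) NULL else add_len(fr, t_rem))
    }
    if (stats::runif(1L) < mu / (lam + mu)) return(NULL)  # loss
    a <- evolve(t_rem - t_ev, v, continue)
    b <- evolve(t_rem - t_ev, v, continue)
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a) || is.null(b)) {
      fr <- if (is.null(a)) b else a
      return(add_len(fr, t_ev))
    }
    dups[[length(dups) + 1L]] <<- data.frame(species_node = v, type = "bd",
                                             stringsAsFactors = FALSE)
    frag_node(list(a, b), len = t_ev)
  }
  # one gene lineage entering the stem branch of species node v
  gene_down <- function(v) {
    stem <- .stem_length(sp, v)
    continue <- function() {
      if (v <= ntip) return(frag_tip(tip_label(sp$tip.label[v])))
      ch_frags <- Filter(Negate(is.null), lapply(kids[[v]], gene_down))
      if (length(ch_frags) == 0L) return(NULL)
      if (length(ch_frags) == 1L) return(ch_frags[[1L]])
      frag_node(ch_frags)
    }
    one_copy <- function() evolve(stem, v, continue)
    wix <- match(v, config$wgd_nodes)
    if (!is.na(wix)) {
      copies <- list(one_copy())
      if (stats::runif(1L) < config$wgd_retention[wix])
        copies <- c(copies, list(one_copy()))
      copies <- Filter(Negate(is.null), copies)
      if (length(copies) == 0L) return(NULL)
      if (length(copies) == 1L) return(copies[[1L]])
      dups[[length(dups) + 1L]] <<- data.frame(species_node = v,
                                               type = "wgd",
                                               stringsAsFactors = FALSE)
      return(frag_node(copies))
    }
    one_copy()
  }
  root <- .root_node(sp)
  ch_frags <- Filter(Negate(is.null), lapply(kids[[root]], gene_down))
  fr <- if (length(ch_frags) == 0L) NULL
        else if (length(ch_frags) == 1L) ch_frags[[1L]]
        else frag_node(ch_frags)
  truth <- list(dups = if (length(dups)) do.call(rbind, dups) else
    data.frame(species_node = integer(), type = character(),
               stringsAsFactors = FALSE))
  n_tips <- function(f) {
    if (is.null(f)) return(0L)
    if (!is.null(f$tip)) return(1L)
    sum(vapply(f$children, n_tips, integer(1)))
  }
  if (is.null(fr) || n_tips(fr) < 2L)
    return(list(time_tree = NULL, truth = truth, family = family_index))
  to_newick <- function(f) {
    if (!is.null(f$tip))
      return(paste0(f$tip, ":", format(f$len, digits = 10)))
    inner <- paste(vapply(f$children, to_newick, character(1)),
                   collapse = ",")
    paste0("(", inner, "):", format(f$len, digits = 10))
  }
  tree <- read_newick(text = paste0(to_newick(fr), ";"))
  list(time_tree = tree, truth = truth, family = family_index)
}

#' Assign dS and dN branch lengths to a gene time tree
#'
#' Each branch's rate is the base rate times lognormal noise, times the
#' herbaceous multiplier when every descendant tip of the branch is
#' herbaceous; branch length = time x rate.
#'
#' @param time_tree A gene `phylo` tree with time branch lengths.
#' @param config A [sim_config()].
#' @param seed Seed for the per-branch noise.
#' @return A [rate_trees()] object; the per-branch truth multiplier is in
#'   the `"herb_branch"` attribute.
#' @export
assign_branch_lengths <- function(time_tree, config, seed = config$seed) {
  tm <- config$species$tm
  ntip <- length(time_tree$tip.label)
  desc <- phangorn::Descendants(time_tree,
                                seq_len(ntip + time_tree$Nnode), "tips")
  habit <- habit_of(tm, taxon_of(tm, time_tree$tip.label))
  herb_node <- vapply(seq_len(ntip + time_tree$Nnode), function(v) {
    h <- habit[desc[[v]]]
    length(h) > 0 && !anyNA(h) && all(h == "H")
  }, logical(1))
  herb_edge <- herb_node[time_tree$edge[, 2L]]
  ne <- nrow(time_tree$edge)
  noise <- .with_seed(seed, matrix(stats::rlnorm(2L * ne,
                                                 meanlog = 0,
                                                 sdlog = config$rate_sdlog),
                                   ncol = 2L))
  ds <- time_tree$edge.length * config$base_ds * noise[, 1L] *
    ifelse(herb_edge, config$herb_multiplier_ds, 1)
  dn <- time_tree$edge.length * config$base_dn * noise[, 2L] *
    ifelse(herb_edge, config$herb_multiplier_dn, 1)
  out <- rate_trees(time_tree, ds, dn)
  attr(out, "herb_branch") <- herb_edge
  out
}

#' Simulate a homolog tree as seen by the curation stage
#'
#' Converts a simulated family to a substitutions/site gene tree with
#' synthetic bootstrap supports, then injects assembly artifacts:
#' near-identical isoform sister tips and (per family, with the
#' configured probability) one spuriously long terminal branch.
#'
#' @param config A [sim_config()].
#' @param family_index Family number.
#' @return List with `tree` (artifact-bearing `phylo` in
#'   substitutions/site, `NULL` for extinct families), `rates`
#'   (clean-topology [rate_trees()]), `truth` (duplications plus
#'   `isoforms` and `contaminants` character vectors of tip labels).
#' @export
simulate_homolog_tree <- function(config, family_index) {
  fam <- simulate_family(config, family_index)
  if (is.null(fam$time_tree))
    return(list(tree = NULL, rates = NULL,
                truth = c(fam$truth, list(isoforms = character(0),
                                          contaminants = character(0)))))
  seed <- .sub_seeds(config$seed + 1L, family_index)[family_index]
  rates <- assign_branch_lengths(fam$time_tree, config, seed = seed)
  .with_seed(seed + 1L, {
    tree <- rates$topology
    tree$edge.length <- rates$ds
    # synthetic bootstrap supports
    tree$node.label <- as.character(round(stats::runif(
      tree$Nnode, config$support_range[1L], config$support_range[2L])))
    isoforms <- character(0)
    for (tip in tree$tip.label) {
      if (stats::runif(1L) < config$isoform_rate) {
        iso <- paste0(tip, "iso")
        tree <- .add_sister_tip(tree, tip, iso, 0.005)
        isoforms <- c(isoforms, iso)
      }
    }
    contaminants <- character(0)
    if (stats::runif(1L) < config$contaminant_rate) {
      victim <- sample(tree$tip.label, 1L)
      i <- .edge_to(tree, match(victim, tree$tip.label))
      tree$edge.length[i] <- tree$edge.length[i] + 3.0
      contaminants <- victim
    }
    list(tree = tree, rates = rates,
         truth = c(fam$truth, list(isoforms = isoforms,
                                   contaminants = contaminants)))
  })
}

#' Attach a new sister tip next to an existing tip
#' @noRd
.add_sister_tip <- function(tree, tip, new_label, dist) {
  i <- match(tip, tree$tip.label)
  stem <- .stem_length(tree, i)
  new_tip <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                            tip.label = new_label,
                            edge.length = dist,
                            Nnode = 1L), class = "phylo")
  at <- max(stem - dist, stem * 0.5)
  out <- ape::bind.tree(tree, new_tip, where = i, position = min(at, stem))
  out
}

#' Simulate a bundle of homolog trees
#'
#' @param config A [sim_config()].
#' @return List of [simulate_homolog_tree()] results (extinct families
#'   are kept as `NULL`-tree entries so indices match family numbers).
#' @export
simulate_bundle <- function(config) {
  lapply(seq_len(config$n_families),
         function(i) simulate_homolog_tree(config, i))
}

#' Write a simulated bundle to plain-text fixtures
#'
#' Writes one newick per family (`fam<N>.nwk`), the taxon map
#' (`taxa.tsv`, `clades.tsv`), contrast definitions (`contrasts.tsv`),
#' and the truth records (`truth.json`). Byte-reproducible from the
#' config seed.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
emit_fixtures <- function(bundle, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(bundle)) {
    if (is.null(bundle[[i]]$tree)) next
    write_newick(bundle[[i]]$tree,
                 file = file.path(dir, sprintf("fam%03d.nwk", i)))
  }
  tm <- config$species$tm
  write_taxon_map(tm, file.path(dir, "taxa.tsv"),
                  file.path(dir, "clades.tsv"))
  defs <- do.call(rbind, lapply(config$species$contrasts, function(d)
    data.frame(label = d$label,
               side = c(rep("W", length(d$woody)),
                        rep("H", length(d$herbaceous))),
               taxon = c(d$woody, d$herbaceous),
               stringsAsFactors = FALSE)))
  utils::write.table(defs, file.path(dir, "contrasts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- lapply(bundle, function(b) list(
    dups = b$truth$dups, isoforms = b$truth$isoforms,
    contaminants = b$truth$contaminants))
  jsonlite::write_json(list(seed = config$seed, families = truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

# ---- codon-pair simulation for Ks ----------------------------------------

#' Simulate a paralog codon-sequence pair at a target Ks
#'
#' Builds a random sense-codon sequence and introduces the number of
#' synonymous (and optionally nonsynonymous) single-nucleotide changes
#' that corresponds to the target distance under the NG86 correction
#' (p = (3/4)(1 - exp(-(4/3) d)), differences = round(p x sites)).
#'
#' @param n_codons Number of codons.
#' @param ks_target Target synonymous distance.
#' @param ka_target Target nonsynonymous distance (default 0).
#' @param seed Integer seed.
#' @return List with `cds1`, `cds2` (nucleotide strings), `pep`
#'   (shared peptide when `ka_target` is 0) and the realized change
#'   counts `n_syn`, `n_nonsyn`.
#' @export
sim_paralog_pair <- function(n_codons = 300, ks_target = 0.6,
                             ka_target = 0, seed = 1) {
  .with_seed(seed, {
    code <- .genetic_code()
    sense <- names(code)[code != "*"]
    syn_sites <- .codon_syn_sites()
    codons <- sample(sense, n_codons, replace = TRUE)
    # synonymous single-step neighbors per codon
    syn_alt <- function(cd) {
      chars <- strsplit(cd, "")[[1L]]
      out <- character(0)
      for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"),
                                          chars[pos])) {
        alt <- chars; alt[pos] <- nt
        acd <- paste(alt, collapse = "")
        if (code[acd] != "*" && code[acd] == code[cd]) out <- c(out, acd)
      }
      out
    }
    nonsyn_alt <- function(cd) {
      chars <- strsplit(cd, "")[[1L]]
      out <- character(0)
      for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"),
                                          chars[pos])) {
        alt <- chars; alt[pos] <- nt
        acd <- paste(alt, collapse = "")
        if (code[acd] != "*" && code[acd] != code[cd]) out <- c(out, acd)
      }
      out
    }
    S <- sum(syn_sites[codons])
    N <- 3 * n_codons - S
    p_of <- function(d) 3 / 4 * (1 - exp(-4 / 3 * d))
    n_syn <- round(p_of(ks_target) * S)
    n_nonsyn <- round(p_of(ka_target) * N)
    mutated <- codons
    can_syn <- which(vapply(codons, function(cd) length(syn_alt(cd)) > 0,
                            logical(1)))
    pick <- sample(can_syn, min(n_syn, length(can_syn)))
    for (i in pick) {
      alts <- syn_alt(mutated[i])
      mutated[i] <- alts[sample.int(length(alts), 1L)]
    }
    if (n_nonsyn > 0) {
      rest <- setdiff(seq_len(n_codons), pick)
      can_non <- rest[vapply(codons[rest],
                             function(cd) length(nonsyn_alt(cd)) > 0,
                             logical(1))]
      pick2 <- sample(can_non, min(n_nonsyn, length(can_non)))
      for (i in pick2) {
        alts <- nonsyn_alt(mutated[i])
        mutated[i] <- alts[sample.int(length(alts), 1L)]
      }
    } else {
      pick2 <- integer(0)
    }
    pep <- paste(code[codons], collapse = "")
    list(cds1 = paste(codons, collapse = ""),
         cds2 = paste(mutated, collapse = ""),
         pep = pep, n_syn = length(pick), n_nonsyn = length(pick2))
  })
}
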