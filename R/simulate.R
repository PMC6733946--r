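#' Simulate a rooted species tree
#'
#' Pure-birth topology via [ape::rphylo()]. In ultrametric mode the
#' coalescent-style branch lengths are kept (equal root-to-tip depths);
#' otherwise branch lengths are redrawn i.i.d. exponential with mean
#' `branch_mean`, emulating a substitutions-per-site phylogram.
#'
#' @param n_taxa Number of leaves (at least 3).
#' @param seed Integer seed.
#' @param ultrametric Keep the ultrametric pure-birth branch lengths.
#' @param branch_mean Mean branch length for the phylogram mode (default 0.2
#'   expected substitutions/site, a typical interordinal scale).
#' @return A validated `phylo` with tip labels `s1..` and internal labels
#'   `N1..`.
#' @export
simulate_species_tree <- function(n_taxa, seed, ultrametric = FALSE,
                                  branch_mean = 0.2) {
  if (n_taxa < 3L) stop("n_taxa must be at least 3")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  if (!ultrametric) {
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / branch_mean)
  }
  tree$tip.label <- paste0("s", seq_len(n_taxa))
  tree$node.label <- paste0("N", seq_len(tree$Nnode))
  validate_species_tree(tree)
}

#' Default configuration for the gene-family history simulator
#'
#' Rates are events per copy per unit branch length. The defaults describe a
#' genome with moderate turnover: duplication rate 0.5, loss rate 0.3 and no
#' origin-branch elevation (`origin_elevation = 1`); elevated-rate scenarios
#' set `origin_elevation` explicitly.
#'
#' @param dup_rate Duplication rate per copy per unit length.
#' @param loss_rate Loss rate per copy per unit length.
#' @param origin_elevation Multiplier applied to the duplication rate on
#'   `ORIGIN`-class branches.
#' @param origin_weights Optional named vector of sampling weights over
#'   internal node ids for the per-family gain node; default uniform over
#'   internal in-group nodes.
#' @return Named list of simulator settings.
#' @export
sim_family_config <- function(dup_rate = 0.5, loss_rate = 0.3,
                              origin_elevation = 1, origin_weights = NULL) {
  list(dup_rate = dup_rate, loss_rate = loss_rate,
       origin_elevation = origin_elevation, origin_weights = origin_weights)
}

#' Simulate gene-family histories with single-gain Dollo structure
#'
#' Each family is gained once at a sampled origin node and then evolves by a
#' per-copy linear birth-death process along every branch below the origin:
#' each live copy duplicates at the (possibly origin-elevated) duplication
#' rate and dies at the loss rate, both per unit branch length. The surviving
#' copy genealogy becomes the true gene tree (all supports 1); every raw
#' event is recorded on the branch where it happened, so that replaying the
#' raw event map reproduces the true copy count at every node exactly.
#' Families with no surviving copies are redrawn and counted.
#'
#' @param stree Species tree (`phylo`).
#' @param classification Output of [classify_branches()]; used for the
#'   origin-branch elevation and to restrict sampled gain nodes to in-group
#'   branches.
#' @param config Output of [sim_family_config()].
#' @param n_families Number of (surviving) families to generate.
#' @param seed Integer seed.
#' @return List of class `family_simulation`: `families` (membership table
#'   `family`, `gene`, `species`), `gene_trees` (named list of `phylo`,
#'   `NULL` for single-copy families), `truth` (per family: `origin`,
#'   `events` data frame of raw per-branch counts, `extant` named vector,
#'   `visible_dups` per-branch duplications retained in the pruned gene
#'   tree), `redraws`, `config`, `seed`.
#' @export
simulate_family_evolution <- function(stree, classification, config,
                                      n_families, seed) {
  stree <- validate_species_tree(stree, assert_root = TRUE)
  set.seed(seed)
  ids <- node_ids(stree)
  ntip <- ape::Ntip(stree)
  ch <- children_list(stree)
  blen <- numeric(length(ids))
  blen[stree$edge[, 2L]] <- stree$edge.length
  branch_class <- stats::setNames(classification$class, classification$branch)
  elev <- ifelse(!is.na(branch_class[ids]) & branch_class[ids] == "ORIGIN",
                 config$origin_elevation, 1)
  internal <- (ntip + 1L):length(ids)
  ingroup <- internal[!(ids[internal] %in%
                          classification$branch[classification$class == "EXCLUDED"])]
  w <- config$origin_weights
  if (is.null(w)) {
    w <- stats::setNames(rep(1, length(ingroup)), ids[ingroup])
  }
  origin_pool <- node_number(stree, names(w))

  fam_rows <- list(); gene_trees <- list(); truth <- list()
  redraws <- 0L
  f <- 0L
  while (f < n_families) {
    origin <- origin_pool[sample.int(length(origin_pool), 1L, prob = w)]
    env <- new.env()
    env$dup <- numeric(length(ids)); env$loss <- numeric(length(ids))
    env$vis_dup <- numeric(length(ids))
    env$gene_counter <- stats::setNames(integer(ntip), stree$tip.label)
    g <- sim_copy_at(origin, stree, ch, blen, elev, config, env, ntip)
    if (is.null(g)) { redraws <- redraws + 1L; next }
    f <- f + 1L
    fam <- sprintf("fam%04d", f)
    leaves <- glist_leaves(g)
    sp <- sub("_g[0-9]+$", "", leaves)
    fam_rows[[f]] <- data.frame(family = fam, gene = leaves, species = sp,
                                stringsAsFactors = FALSE)
    gene_trees[[fam]] <- if (length(leaves) >= 2L) glist_to_phylo(g) else NULL
    has_ev <- env$dup > 0 | env$loss > 0
    truth[[fam]] <- list(
      origin = ids[origin],
      events = data.frame(branch = ids[has_ev],
                          duplications = env$dup[has_ev],
                          losses = env$loss[has_ev],
                          stringsAsFactors = FALSE),
      visible_dups = stats::setNames(env$vis_dup[env$vis_dup > 0],
                                     ids[env$vis_dup > 0]),
      extant = table(factor(sp, levels = stree$tip.label))
    )
  }
  structure(list(
    families = do.call(rbind, fam_rows),
    gene_trees = gene_trees,
    truth = truth,
    redraws = redraws,
    config = config,
    seed = seed
  ), class = "family_simulation")
}

# a copy alive at species node `snode`; returns the pruned gene subtree
# (glist) of its surviving descendants, or NULL
sim_copy_at <- function(snode, stree, ch, blen, elev, config, env, ntip) {
  if (snode <= ntip) {
    env$gene_counter[snode] <- env$gene_counter[snode] + 1L
    return(list(leaf = TRUE,
                label = paste0(stree$tip.label[snode], "_g",
                               env$gene_counter[snode])))
  }
  kids <- ch[[snode]]
  subs <- list()
  for (k in kids) {
    s <- sim_copy_edge(k, blen[k], stree, ch, blen, elev, config, env, ntip)
    if (!is.null(s)) subs <- c(subs, list(s))
  }
  if (length(subs) == 0L) return(NULL)
  if (length(subs) == 1L) return(subs[[1L]])
  list(leaf = FALSE, support = 1, children = subs)
}

# a copy descending the branch into species node `snode` with `trem` branch
# length remaining
sim_copy_edge <- function(snode, trem, stree, ch, blen, elev, config, env,
                          ntip) {
  b <- config$dup_rate * elev[snode]
  d <- config$loss_rate
  repeat {
    if (b + d <= 0) return(sim_copy_at(snode, stree, ch, blen, elev, config,
                                       env, ntip))
    wait <- stats::rexp(1L, b + d)
    if (wait >= trem) {
      return(sim_copy_at(snode, stree, ch, blen, elev, config, env, ntip))
    }
    trem <- trem - wait
    if (stats::runif(1L) < b / (b + d)) {
      env$dup[snode] <- env$dup[snode] + 1
      left <- sim_copy_edge(snode, trem, stree, ch, blen, elev, config, env,
                            ntip)
      right <- sim_copy_edge(snode, trem, stree, ch, blen, elev, config, env,
                             ntip)
      if (is.null(left) && is.null(right)) return(NULL)
      if (is.null(left)) return(right)
      if (is.null(right)) return(left)
      env$vis_dup[snode] <- env$vis_dup[snode] + 1
      return(list(leaf = FALSE, support = 1, children = list(left, right)))
    }
    env$loss[snode] <- env$loss[snode] + 1
    return(NULL)
  }
}

#' Event map from simulated ground truth
#'
#' Converts the raw event records of a [simulate_family_evolution()] run into
#' an `event_map` (gain on the branch subtending the true origin node), the
#' exact per-branch history against which reconciliation-based maps can be
#' compared.
#'
#' @param sim A `family_simulation`.
#' @return An `event_map`.
#' @export
truth_event_map <- function(sim) {
  rows <- list()
  origins <- vapply(sim$truth, function(t) t$origin, character(1))
  for (fam in names(sim$truth)) {
    t <- sim$truth[[fam]]
    branches <- sort(unique(c(t$origin, t$events$branch)))
    i <- match(t$events$branch, branches)
    dup <- numeric(length(branches)); dup[i] <- t$events$duplications
    loss <- numeric(length(branches)); loss[i] <- t$events$losses
    rows[[fam]] <- data.frame(
      family = fam, branch = branches,
      gain = as.integer(branches == t$origin),
      duplications = as.integer(dup), losses = as.integer(loss),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, origins = origins, class = c("event_map", "data.frame"))
}

#' Simulate families with branch-wise Poisson duplications
#'
#' Calibration-oriented generator for the rate screen: every family is
#' present in all species (gain at the root), never lost, and accumulates
#' duplications independently on each included branch as
#' `Poisson(dup_rate x length x elevation)`, where the elevation factor
#' applies on `ORIGIN`-class branches only. With `origin_elevation = 1` this
#' is an exchangeable null for the permutation ANOVA (per-branch rates are
#' i.i.d. up to branch length); with an elevation factor it provides a
#' clean alternative with a known effect size. Each duplication adds one
#' copy to every leaf below its branch, so ancestral copy numbers stay
#' consistent.
#'
#' @param stree Species tree (`phylo`).
#' @param classification Output of [classify_branches()].
#' @param n_families Number of families.
#' @param dup_rate Expected duplications per unit branch length.
#' @param origin_elevation Rate multiplier on `ORIGIN` branches (default 1).
#' @param seed Integer seed.
#' @return An `event_map` (origins all at the root).
#' @export
simulate_poisson_dup_families <- function(stree, classification, n_families,
                                          dup_rate, origin_elevation = 1,
                                          seed = 1L) {
  stree <- validate_species_tree(stree, assert_root = TRUE)
  set.seed(seed)
  keep <- classification[classification$class %in%
                           c("PRE_ORIGIN", "ORIGIN", "POST_ORIGIN"), ]
  mu <- dup_rate * keep$length *
    ifelse(keep$class == "ORIGIN", origin_elevation, 1)
  root_id <- node_ids(stree)[root_number(stree)]
  rows <- vector("list", n_families)
  fams <- sprintf("null%04d", seq_len(n_families))
  for (i in seq_len(n_families)) {
    dups <- stats::rpois(length(mu), mu)
    rows[[i]] <- data.frame(
      family = fams[i],
      branch = c(root_id, keep$branch),
      gain = c(1L, integer(length(mu))),
      duplications = c(0L, dups),
      losses = 0L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[out$gain > 0L | out$duplications > 0L, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            origins = stats::setNames(rep(root_id, n_families), fams),
            class = c("event_map", "data.frame"))
}

#' Simulate a binary trait under the forward threshold model
#'
#' Liabilities diffuse from the root by Brownian motion (variance equal to
#' branch length, rate 1) via [phytools::fastBM()]; the observed state of a
#' tip is `hyphal` when its liability exceeds 0.
#'
#' @param stree Species tree (`phylo`) with positive branch lengths.
#' @param seed Integer seed.
#' @param root_liability Liability at the root (default 0: maximally
#'   uncertain ancestral state).
#' @return List with `states` (named character, tips), `liabilities` (named
#'   numeric over all node ids, tips first).
#' @export
simulate_trait <- function(stree, seed, root_liability = 0) {
  stree <- validate_species_tree(stree, assert_root = TRUE)
  set.seed(seed)
  x <- phytools::fastBM(stree, a = root_liability, sig2 = 1, internal = TRUE)
  liab <- stats::setNames(as.numeric(x), node_ids(stree))
  states <- ifelse(liab[stree$tip.label] > 0, "hyphal", "non_hyphal")
  list(states = states, liabilities = liab)
}

#' Default feature-simulation configuration
#'
#' Per-group length and count distributions for the gene-structure and
#' domain-architecture generators. Defaults emulate fungal gene models:
#' multicellular species carry more and slightly longer exons, longer
#' introns and more domains per protein than plesiomorphically unicellular
#' species.
#'
#' @param unicellular,multicellular Named lists with `n_cds_mean` (mean
#'   number of CDS segments above 1), `cds_seg_mean` (mean segment length,
#'   nt), `intron_mean` (mean intron length, nt), `domain_mean` (mean domain
#'   count above 1).
#' @return Named list of group configurations.
#' @export
sim_feature_config <- function(
    unicellular = list(n_cds_mean = 1.5, cds_seg_mean = 400,
                       intron_mean = 80, domain_mean = 1),
    multicellular = list(n_cds_mean = 3.5, cds_seg_mean = 450,
                         intron_mean = 100, domain_mean = 2)) {
  list(unicellular = unicellular, multicellular = multicellular)
}

#' Simulate gene models and domain tables for two cellularity groups
#'
#' Writes one GFF3 file per group (genes laid head to tail on a single
#' contig, alternating strands, gene span equal to the CDS plus introns) and
#' a combined domain-annotation TSV, together with the exact sampled lengths
#' for round-trip testing.
#'
#' @param config Output of [sim_feature_config()].
#' @param n_genes Genes per group.
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @return List with `gff` (named file paths), `domains` (data frame
#'   `protein`, `species`, `group`, `family`, `n_domains`, `architecture`),
#'   `truth` (per-gene sampled CDS/intron lengths).
#' @export
simulate_features <- function(config, n_genes, seed, dir = tempfile("feat")) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff_paths <- character(0)
  truth_rows <- list(); domain_rows <- list()
  pfam_pool <- sprintf("PF%05d", 1:40)
  for (grp in names(config)) {
    cfg <- config[[grp]]
    lines <- "##gff-version 3"
    pos <- 1L
    sp <- paste0(grp, "_sp1")
    for (i in seq_len(n_genes)) {
      gid <- sprintf("%s_gene%04d", grp, i)
      n_cds <- 1L + stats::rpois(1L, cfg$n_cds_mean)
      seg <- 30L + stats::rpois(n_cds, cfg$cds_seg_mean - 30)
      intr <- if (n_cds > 1L) 20L + stats::rpois(n_cds - 1L, cfg$intron_mean - 20)
              else integer(0)
      starts <- integer(n_cds); ends <- integer(n_cds)
      cur <- pos
      for (k in seq_len(n_cds)) {
        starts[k] <- cur; ends[k] <- cur + seg[k] - 1L
        cur <- ends[k] + 1L + (if (k < n_cds) intr[k] else 0L)
      }
      strand <- if (i %% 2L == 0L) "-" else "+"
      gstart <- starts[1L]; gend <- ends[n_cds]
      attr_g <- paste0("ID=", gid)
      mid <- paste0(gid, ".t1")
      lines <- c(lines,
        paste("chr1", "sim", "gene", gstart, gend, ".", strand, ".",
              attr_g, sep = "\t"),
        paste("chr1", "sim", "mRNA", gstart, gend, ".", strand, ".",
              paste0("ID=", mid, ";Parent=", gid), sep = "\t"),
        vapply(seq_len(n_cds), function(k)
          paste("chr1", "sim", "CDS", starts[k], ends[k], ".", strand, "0",
                paste0("ID=", mid, ".cds", k, ";Parent=", mid), sep = "\t"),
          character(1)))
      pos <- gend + 500L
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        group = grp, gene = gid, gene_length = gend - gstart + 1L,
        cds_length = sum(seg), n_cds = n_cds,
        total_intron_length = sum(intr), stringsAsFactors = FALSE)
      n_dom <- 1L + stats::rpois(1L, cfg$domain_mean)
      doms <- sample(pfam_pool, n_dom, replace = TRUE)
      domain_rows[[length(domain_rows) + 1L]] <- data.frame(
        protein = paste0(gid, ".p1"), species = sp, group = grp,
        family = sprintf("df%03d", 1L + (i - 1L) %% 20L),
        n_domains = n_dom, architecture = paste(doms, collapse = ">"),
        stringsAsFactors = FALSE)
    }
    path <- file.path(dir, paste0("genes_", grp, ".gff3"))
    writeLines(lines, path)
    gff_paths[grp] <- path
  }
  domains <- do.call(rbind, domain_rows)
  utils::write.table(domains, file.path(dir, "domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(gff = gff_paths, domains = domains,
       truth = do.call(rbind, truth_rows))
}
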