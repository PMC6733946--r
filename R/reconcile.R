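#' @name reconciliation
#' @title Gene-tree / species-tree reconciliation
#'
#' @description
#' Duplication and loss events are inferred for each gene family by mapping
#' its rooted gene tree onto the species tree under the LCA rule: every gene
#' tree node is mapped to the most recent common ancestor (in the species
#' tree) of the species of its leaves, and a node is a duplication if and
#' only if it maps to the same species node as at least one of its children.
#' Weakly supported gene-tree edges are collapsed first and the resulting
#' polytomies re-resolved so as to minimize the duplication count, mirroring
#' the common practice of rearranging poorly supported edges before counting
#' events.
NULL

# ---- internal recursive gene-tree representation --------------------------
# leaf:     list(leaf = TRUE,  label = <gene id>)
# internal: list(leaf = FALSE, support = <numeric or NA>, children = list())

phylo_to_glist <- function(tree) {
  ch <- children_list(tree)
  ntip <- ape::Ntip(tree)
  lab <- tree$node.label
  rec <- function(v) {
    if (v <= ntip) return(list(leaf = TRUE, label = tree$tip.label[v]))
    sup <- NA_real_
    if (!is.null(lab)) {
      s <- suppressWarnings(as.numeric(lab[v - ntip]))
      if (length(s) == 1L && !is.na(s)) sup <- s
    }
    list(leaf = FALSE, support = sup, children = lapply(ch[[v]], rec))
  }
  rec(root_number(tree))
}

glist_to_newick <- function(g) {
  rec <- function(node) {
    if (isTRUE(node$leaf)) return(node$label)
    sup <- if (is.na(node$support)) "" else format(node$support, digits = 15)
    paste0("(", paste(vapply(node$children, rec, character(1)), collapse = ","),
           ")", sup)
  }
  paste0(rec(g), ";")
}

glist_to_phylo <- function(g) {
  ape::read.tree(text = glist_to_newick(g))
}

glist_leaves <- function(g) {
  if (isTRUE(g$leaf)) return(g$label)
  unlist(lapply(g$children, glist_leaves))
}

#' Collapse weakly supported gene-tree edges
#'
#' Contracts every internal (non-root, non-leaf) edge whose support value is
#' below `threshold`, reattaching the child's children to its parent. Edges
#' without a support annotation are never collapsed (treated as fully
#' supported), and leaf edges are exempt by construction.
#'
#' @param gtree Rooted gene tree (`phylo`); internal node labels are read as
#'   numeric support values in `[0, 1]`.
#' @param threshold Support threshold; edges with support strictly below it
#'   are contracted. The headline analysis uses 0.9 for SH-like supports.
#' @return A `phylo` object, possibly multifurcating.
#' @export
collapse_weak_edges <- function(gtree, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  sup <- gene_tree_supports(gtree)
  if (any(!is.na(sup) & (sup < 0 | sup > 1))) {
    stop("gene-tree support values must lie in [0, 1]")
  }
  g <- phylo_to_glist(gtree)
  rec <- function(node) {
    if (isTRUE(node$leaf)) return(node)
    node$children <- lapply(node$children, rec)
    kept <- list()
    for (child in node$children) {
      if (!isTRUE(child$leaf) && !is.na(child$support) &&
          child$support < threshold) {
        kept <- c(kept, child$children)     # contract: splice grandchildren up
      } else {
        kept <- c(kept, list(child))
      }
    }
    node$children <- kept
    node
  }
  glist_to_phylo(rec(g))
}

gene_tree_supports <- function(gtree) {
  if (is.null(gtree$node.label)) return(rep(NA_real_, gtree$Nnode))
  suppressWarnings(as.numeric(gtree$node.label))
}

#' Resolve gene-tree polytomies to minimize duplications
#'
#' Each polytomy is replaced by a binary subtree chosen greedily: the pair of
#' child subtrees whose joint species set has the deepest MRCA on the species
#' tree is joined first, ties broken lexicographically by the smallest leaf
#' label of the candidate pair. This deterministic policy stands in for a full
#' duplication-loss rearrangement search.
#'
#' @param gtree Rooted, possibly multifurcating gene tree (`phylo`).
#' @param stree Species tree (`phylo`).
#' @param species Named character vector mapping gene ids to species labels.
#' @return A rooted binary `phylo` gene tree.
#' @export
resolve_polytomies_min_dup <- function(gtree, stree, species) {
  stree <- validate_species_tree(stree, assert_root = TRUE)
  depth <- depth_vector(stree)
  par <- parent_vector(stree)

  mrca_num <- function(tipnums) {
    # walk-up MRCA over species node numbers
    cur <- tipnums[1L]
    for (v in tipnums[-1L]) cur <- mrca_pair(cur, v, par, depth)
    cur
  }

  rec <- function(node) {
    if (isTRUE(node$leaf)) return(node)
    node$children <- lapply(node$children, rec)
    while (length(node$children) > 2L) {
      units <- node$children
      k <- length(units)
      uleaves <- lapply(units, glist_leaves)
      usp <- lapply(uleaves, function(lv) {
        unique(match(unname(species[lv]), stree$tip.label))
      })
      umin <- vapply(uleaves, min, character(1))
      best <- NULL
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        d <- depth[mrca_num(unique(c(usp[[i]], usp[[j]])))]
        key <- sort(c(umin[i], umin[j]))
        if (is.null(best) || d > best$d ||
            (d == best$d && (key[1L] < best$key[1L] ||
             (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
      joined <- list(leaf = FALSE, support = NA_real_,
                     children = list(units[[best$i]], units[[best$j]]))
      node$children <- c(units[-c(best$i, best$j)], list(joined))
    }
    node
  }
  g <- rec(phylo_to_glist(gtree))
  glist_to_phylo(g)
}

# MRCA of two species-tree node numbers by walking up to equal depth
mrca_pair <- function(a, b, par, depth) {
  while (depth[a] > depth[b]) a <- par[a]
  while (depth[b] > depth[a]) b <- par[b]
  while (a != b) { a <- par[a]; b <- par[b] }
  a
}

#' LCA reconciliation of a binary gene tree with the species tree
#'
#' Maps every gene-tree node to the species-tree MRCA of its leaf species,
#' flags duplications (node mapping equal to a child's mapping), and places
#' the implied losses on species branches. For a gene-tree edge from parent
#' `g` to child `c` the copy silently skips the species nodes strictly
#' between `M(g)` and `M(c)`; one loss is charged to the branch of each
#' off-path child at every skipped node, and additionally at `M(g)` itself
#' when `g` is a duplication whose child maps below it. On a binary species
#' tree the per-edge loss count equals `d(M(g), M(c)) - 1 + [g dup and
#' M(c) != M(g)]` where `d` counts species-tree edges between the mappings.
#'
#' @param gtree Rooted binary gene tree (`phylo`), tips labeled by gene id.
#' @param stree Species tree (`phylo`).
#' @param species Named character vector mapping gene ids to species labels.
#' @return An object of class `reconciled_tree`: a list with the gene tree,
#'   per-node species mappings (`mapping`, node identifiers), per-node events
#'   (`"S"`/`"D"` for internal nodes, `"T"` for tips), the per-branch event
#'   table `counts` (columns `branch`, `duplications`, `losses`) and the
#'   extant per-species copy counts.
#' @export
lca_reconcile <- function(gtree, stree, species) {
  stree <- validate_species_tree(stree, assert_root = TRUE)
  if (!ape::is.rooted(gtree)) stop("gene tree must be rooted")
  if (!ape::is.binary(gtree)) stop("gene tree must be binary; resolve polytomies first")
  ntip_g <- ape::Ntip(gtree)
  nnode_g <- ntip_g + gtree$Nnode
  sp <- unname(species[gtree$tip.label])
  if (anyNA(sp)) {
    stop("gene(s) without species assignment: ",
         paste(gtree$tip.label[is.na(sp)], collapse = ", "))
  }
  spnum <- match(sp, stree$tip.label)
  if (anyNA(spnum)) {
    stop("species not in species tree: ",
         paste(unique(sp[is.na(spnum)]), collapse = ", "))
  }
  par_s <- parent_vector(stree)
  depth_s <- depth_vector(stree)
  ch_s <- children_list(stree)
  ids_s <- node_ids(stree)

  # postorder mapping
  M <- integer(nnode_g)
  M[seq_len(ntip_g)] <- spnum
  ord <- rev(preorder_numbers(gtree))
  ch_g <- children_list(gtree)
  for (v in ord) {
    if (v <= ntip_g) next
    kids <- ch_g[[v]]
    m <- M[kids[1L]]
    for (k in kids[-1L]) m <- mrca_pair(m, M[k], par_s, depth_s)
    M[v] <- m
  }
  event <- rep("T", nnode_g)
  for (v in (ntip_g + 1L):nnode_g) {
    event[v] <- if (any(M[ch_g[[v]]] == M[v])) "D" else "S"
  }

  # losses: walk each gene edge down the species tree
  loss_branch <- integer(0)
  for (i in seq_len(nrow(gtree$edge))) {
    g <- gtree$edge[i, 1L]; c_ <- gtree$edge[i, 2L]
    if (M[c_] == M[g] && event[g] != "D") next
    # species nodes on the path M(c) -> M(g), child side first
    path <- integer(0)
    v <- M[c_]
    while (v != M[g]) { path <- c(path, v); v <- par_s[v] }
    # skipped nodes: strictly between, plus M(g) itself when g is a duplication
    skipped <- if (length(path) > 1L) path[-1L] else integer(0)
    if (event[g] == "D" && M[c_] != M[g]) skipped <- c(skipped, M[g])
    for (j in seq_along(skipped)) {
      s <- skipped[j]
      onpath <- if (j <= length(path) - 1L) path[j] else path[length(path)]
      off <- setdiff(ch_s[[s]], onpath)
      loss_branch <- c(loss_branch, off)
    }
  }
  dup_nodes <- which(event == "D")
  counts <- aggregate_events(ids_s, M[dup_nodes], loss_branch)
  structure(list(
    gtree = gtree,
    species_map = species,
    mapping = ids_s[M],
    event = event,
    counts = counts,
    extant = table(factor(sp, levels = stree$tip.label))
  ), class = "reconciled_tree")
}

aggregate_events <- function(ids_s, dup_nums, loss_nums) {
  branches <- sort(unique(c(dup_nums, loss_nums)))
  data.frame(
    branch = ids_s[branches],
    duplications = as.integer(tabulate(match(dup_nums, branches),
                                       nbins = length(branches))),
    losses = as.integer(tabulate(match(loss_nums, branches),
                                 nbins = length(branches))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.reconciled_tree <- function(x, ...) {
  cat("LCA reconciliation:", ape::Ntip(x$gtree), "genes,",
      sum(x$event == "D"), "duplications,",
      sum(x$counts$losses), "losses\n")
  invisible(x)
}

#' Reconcile a gene tree end to end
#'
#' Convenience wrapper chaining [collapse_weak_edges()],
#' [resolve_polytomies_min_dup()] and [lca_reconcile()].
#'
#' @inheritParams lca_reconcile
#' @param support_threshold Support below which gene-tree edges are collapsed
#'   before re-resolution (default 0.9).
#' @return A `reconciled_tree` object.
#' @export
reconcile_family <- function(gtree, stree, species, support_threshold = 0.9) {
  gt <- collapse_weak_edges(gtree, support_threshold)
  gt <- resolve_polytomies_min_dup(gt, stree, species)
  lca_reconcile(gt, stree, species)
}
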