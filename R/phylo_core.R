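#' Parse a rooted Newick species tree
#'
#' Reads a Newick string into an [ape::phylo] object and validates it as a
#' species tree: a single root, unique non-empty tip labels, and non-negative
#' branch lengths. Internal node labels are treated as node identifiers (not
#' support values); unlabeled internal nodes are assigned stable identifiers
#' of the form `N<number>`. Branch lengths that are missing are replaced by
#' `default_branch_length` with a warning so that downstream rate computations
#' stay defined.
#'
#' @param text A Newick string (must end in `;`).
#' @param default_branch_length Length substituted for missing branch lengths.
#' @param assert_root If the basal node is a multifurcation the tree is only
#'   accepted when `assert_root = TRUE`, because an unrooted Newick file is
#'   indistinguishable from a rooted basal polytomy.
#' @return A validated `phylo` object with complete `node.label`.
#' @export
parse_newick <- function(text, default_branch_length = 1, assert_root = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL
  )
  if (is.null(tree)) {
    # locate the first structurally suspect character for the error message
    off <- newick_error_offset(text)
    stop(sprintf("malformed Newick string (near character %d): %s", off,
                 substr(text, max(1L, off - 10L), off + 10L)), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning(sprintf("tree has no branch lengths; all set to %g",
                    default_branch_length))
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning(sprintf("%d missing branch length(s) set to %g",
                    sum(is.na(tree$edge.length)), default_branch_length))
    tree$edge.length[is.na(tree$edge.length)] <- default_branch_length
  }
  validate_species_tree(tree, assert_root = assert_root)
}

# crude scan for the first unbalanced parenthesis / stray character, used
# only to point the user at the failure location
newick_error_offset <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  nchar(text)
}

#' Validate a phylo object as a species tree
#'
#' @param tree A `phylo` object.
#' @param assert_root Accept a basal multifurcation as a genuine root.
#' @return The tree, with any missing internal node labels filled in.
#' @export
validate_species_tree <- function(tree, assert_root = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (ape::Ntip(tree) < 2L) stop("species tree needs at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop("empty leaf label")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  root <- ape::Ntip(tree) + 1L
  if (sum(tree$edge[, 1L] == root) > 2L && !assert_root) {
    stop("basal node is a multifurcation; pass assert_root = TRUE to accept ",
         "it as a genuine root")
  }
  tree <- fill_node_labels(tree)
  if (anyDuplicated(c(tree$tip.label, tree$node.label))) {
    stop("node identifiers are not unique across tips and internal nodes")
  }
  tree
}

fill_node_labels <- function(tree) {
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  lab[is.na(lab)] <- ""
  empty <- !nzchar(lab)
  if (any(empty)) {
    cand <- paste0("N", seq_len(n_int))
    cand <- setdiff(cand, c(tree$tip.label, lab))
    lab[empty] <- cand[seq_len(sum(empty))]
  }
  tree$node.label <- lab
  tree
}

#' Node identifiers of a species tree
#'
#' Returns the identifier of every node in ape numbering order: tips first
#' (their labels), then internal nodes (their `node.label`).
#'
#' @param tree A `phylo` object with complete `node.label`.
#' @return Character vector of length `Ntip + Nnode`.
#' @export
node_ids <- function(tree) {
  if (is.null(tree$node.label)) tree <- fill_node_labels(tree)
  c(tree$tip.label, tree$node.label)
}

# ape node number for a node identifier (tip label or internal label)
node_number <- function(tree, id) {
  idx <- match(id, node_ids(tree))
  if (anyNA(idx)) {
    stop("unknown node id(s): ", paste(id[is.na(idx)], collapse = ", "))
  }
  idx
}

root_number <- function(tree) ape::Ntip(tree) + 1L

# parent ape-number of every node (0 for the root), indexed by node number
parent_vector <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# list of child ape-numbers per node
children_list <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  }
  ch
}

# number of edges on the path root -> node, indexed by node number
depth_vector <- function(tree) {
  par <- parent_vector(tree)
  n <- length(par)
  d <- integer(n)
  ord <- preorder_numbers(tree)
  for (v in ord) if (par[v] != 0L) d[v] <- d[par[v]] + 1L
  d
}

# node numbers in preorder (root first)
preorder_numbers <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  c(root_number(tree), tree$edge[, 2L])
}

# tip numbers below each node (list indexed by node number)
tips_below <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(ape::Ntip(tree))) out[[i]] <- i
  ord <- rev(preorder_numbers(tree))
  par <- parent_vector(tree)
  for (v in ord) {
    if (par[v] != 0L) out[[par[v]]] <- c(out[[par[v]]], out[[v]])
  }
  out
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree A species tree (`phylo`).
#' @param taxa Non-empty character vector of leaf labels.
#' @return The node identifier of the MRCA (a leaf id for a singleton set).
#' @export
mrca_node <- function(tree, taxa) {
  if (length(taxa) == 0L) stop("taxa must be non-empty")
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) stop("unknown taxa: ", paste(miss, collapse = ", "))
  taxa <- unique(taxa)
  if (length(taxa) == 1L) return(taxa)
  node_ids(tree)[ape::getMRCA(tree, taxa)]
}

#' Classify species-tree branches relative to designated trait-origin nodes
#'
#' Every branch (identified by its child node) is assigned to exactly one
#' class: `ORIGIN` for branches subtending a designated origin node, `EXCLUDED`
#' for the outgroup clade including its stem, `TERMINAL` for leaf branches,
#' `PRE_ORIGIN` for internal in-group branches on the root side of the origin
#' region (ancestors of at least one origin node), and `POST_ORIGIN` for the
#' remaining internal in-group branches. Precedence is EXCLUDED > ORIGIN >
#' TERMINAL > PRE_ORIGIN > POST_ORIGIN.
#'
#' @param tree A species tree (`phylo`).
#' @param origin_nodes Character vector of internal node identifiers at which
#'   the trait is taken to originate.
#' @param outgroup_root Optional identifier of the node spanning the outgroup
#'   clade; that clade and its stem branch are excluded from all analyses.
#' @return A data frame with columns `branch` (child node id), `parent`,
#'   `length` and `class`, one row per edge of the tree.
#' @export
classify_branches <- function(tree, origin_nodes, outgroup_root = NULL) {
  tree <- validate_species_tree(tree, assert_root = TRUE)
  ids <- node_ids(tree)
  onum <- node_number(tree, origin_nodes)
  if (any(onum <= ape::Ntip(tree))) {
    stop("origin node(s) must be internal: ",
         paste(origin_nodes[onum <= ape::Ntip(tree)], collapse = ", "))
  }
  excl <- integer(0)
  if (!is.null(outgroup_root)) {
    og <- node_number(tree, outgroup_root)
    if (og <= ape::Ntip(tree)) stop("outgroup_root must be an internal node")
    excl <- c(og, descendant_numbers(tree, og))
  }
  # ancestors of origin nodes (root side of the origin region)
  par <- parent_vector(tree)
  pre <- integer(0)
  for (v in onum) {
    a <- par[v]
    while (a != 0L) { pre <- c(pre, a); a <- par[a] }
  }
  pre <- unique(pre)
  child <- tree$edge[, 2L]
  cls <- ifelse(child %in% excl, "EXCLUDED",
         ifelse(child %in% onum, "ORIGIN",
         ifelse(child <= ape::Ntip(tree), "TERMINAL",
         ifelse(child %in% pre, "PRE_ORIGIN", "POST_ORIGIN"))))
  data.frame(
    branch = ids[child],
    parent = ids[tree$edge[, 1L]],
    length = tree$edge.length,
    class = cls,
    stringsAsFactors = FALSE
  )
}

# all ape-numbers strictly below a node
descendant_numbers <- function(tree, node) {
  out <- integer(0)
  stack <- node
  ch <- children_list(tree)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    kids <- ch[[v]]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ape::Ntip(tree)])
  }
  out
}

#' Write a branch classification to TSV
#'
#' @param classification Output of [classify_branches()].
#' @param path Output file path.
#' @export
write_classification <- function(classification, path) {
  utils::write.table(classification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
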