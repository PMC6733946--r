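#' Dollo parsimony origin and losses of a gene family
#'
#' Under Dollo parsimony a family is gained exactly once, at the MRCA of the
#' species that carry it, and is thereafter only lost. The minimal loss set
#' places one loss on the stem branch of every maximal carrier-free clade
#' below the origin.
#'
#' @param presence Named integer/logical vector over species-tree leaves
#'   (1/TRUE = family present), or a character vector of carrier species.
#' @param stree Species tree (`phylo`).
#' @return List with `origin` (node identifier) and `loss_branches`
#'   (character vector of species branch ids, identified by child node).
#' @export
dollo_origin <- function(presence, stree) {
  stree <- validate_species_tree(stree, assert_root = TRUE)
  carriers <- presence_to_carriers(presence, stree)
  if (length(carriers) == 0L) stop("family absent from every species; Dollo mapping undefined")
  origin_id <- mrca_node(stree, carriers)
  onum <- node_number(stree, origin_id)
  ids <- node_ids(stree)
  ch <- children_list(stree)
  tb <- tips_below(stree)
  carrier_num <- match(carriers, stree$tip.label)
  losses <- integer(0)
  if (onum > ape::Ntip(stree)) {
    stack <- onum
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      for (k in ch[[v]]) {
        if (!any(tb[[k]] %in% carrier_num)) {
          losses <- c(losses, k)            # maximal absent clade: one stem loss
        } else if (k > ape::Ntip(stree)) {
          stack <- c(stack, k)
        }
      }
    }
  }
  list(origin = origin_id, loss_branches = ids[losses])
}

presence_to_carriers <- function(presence, stree) {
  if (is.character(presence) && is.null(names(presence))) {
    carriers <- unique(presence)
  } else {
    carriers <- names(presence)[as.logical(presence) & !is.na(presence)]
  }
  miss <- setdiff(carriers, stree$tip.label)
  if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
  carriers
}

#' Build the per-family, per-branch event map
#'
#' Combines Dollo gains with reconciliation duplications and losses into a
#' single long-format event table. The gain of each family is recorded on the
#' branch subtending its Dollo origin node (for a family originating at the
#' root, on a pseudo-branch identified by the root node itself), so that the
#' origin node carries at least one copy. Families without a reconciliation
#' are handled in presence-only mode: duplications implied by `k > 1` extant
#' copies in a species are charged to that terminal branch (`k - 1` events),
#' and losses come from the Dollo mapping.
#'
#' @param families Data frame with columns `family`, `gene`, `species` (one
#'   row per extant gene copy).
#' @param stree Species tree (`phylo`).
#' @param reconciliations Optional named list of `reconciled_tree` objects
#'   (names = family ids) supplying duplication/loss placements.
#' @param classification Optional output of [classify_branches()]; when given,
#'   families whose Dollo origin falls inside the excluded (outgroup) clade
#'   are still mapped, but an exclusion mask is available downstream.
#' @return An object of class `event_map`: a data frame with columns
#'   `family`, `branch`, `gain`, `duplications`, `losses`, plus an
#'   `origins` attribute (named character vector family -> origin node id).
#' @export
build_event_map <- function(families, stree, reconciliations = NULL,
                            classification = NULL) {
  stopifnot(all(c("family", "gene", "species") %in% names(families)))
  stree <- validate_species_tree(stree, assert_root = TRUE)
  fam_ids <- unique(families$family)
  rows <- vector("list", length(fam_ids))
  origins <- character(length(fam_ids))
  names(origins) <- fam_ids
  for (i in seq_along(fam_ids)) {
    f <- fam_ids[i]
    sub <- families[families$family == f, , drop = FALSE]
    counts <- table(factor(sub$species, levels = stree$tip.label))
    dol <- dollo_origin(stats::setNames(as.integer(counts > 0),
                                        stree$tip.label), stree)
    origins[i] <- dol$origin
    rec <- reconciliations[[f]]
    if (!is.null(rec)) {
      obs <- as.integer(rec$extant)
      if (!identical(obs, as.integer(counts))) {
        stop("family ", f, ": reconciliation leaf counts disagree with the ",
             "membership table")
      }
      ev <- rec$counts
      dup_b <- rep(ev$branch, ev$duplications)
      # reconciliation losses already cover absent clades below the origin
      loss_b <- rep(ev$branch, ev$losses)
    } else {
      extra <- counts[counts > 1L]
      dup_b <- rep(names(extra), as.integer(extra) - 1L)
      loss_b <- dol$loss_branches
    }
    branches <- sort(unique(c(dol$origin, dup_b, loss_b)))
    rows[[i]] <- data.frame(
      family = f,
      branch = branches,
      gain = as.integer(branches == dol$origin),
      duplications = as.integer(tabulate(match(dup_b, branches),
                                         nbins = length(branches))),
      losses = as.integer(tabulate(match(loss_b, branches),
                                   nbins = length(branches))),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, origins = origins, class = c("event_map", "data.frame"))
}

#' Family origin nodes of an event map
#'
#' @param events An `event_map`.
#' @return Named character vector family -> origin node identifier.
#' @export
event_map_origins <- function(events) attr(events, "origins")

#' Combine event maps of disjoint family sets
#'
#' @param ... `event_map` objects over the same species tree.
#' @return A single `event_map` with the rows and origins concatenated.
#' @export
combine_event_maps <- function(...) {
  maps <- list(...)
  out <- do.call(rbind, lapply(maps, as.data.frame))
  rownames(out) <- NULL
  structure(out,
            origins = do.call(c, lapply(maps, attr, "origins")),
            class = c("event_map", "data.frame"))
}

#' Ancestral copy numbers from an event map
#'
#' The copy number of a family at a node is the sum, over the branches on the
#' path from the root to that node (each branch identified by its child node,
#' plus the root pseudo-branch), of `gain + duplications - losses`. Leaves
#' therefore recover the extant copy counts, and any negative intermediate
#' value indicates an inconsistent event map.
#'
#' @param events An `event_map` (or a data frame with the same columns).
#' @param stree Species tree (`phylo`).
#' @return Integer matrix nodes x families (row names are node identifiers in
#'   ape order, tips first).
#' @export
ancestral_copy_numbers <- function(events, stree) {
  stree <- validate_species_tree(stree, assert_root = TRUE)
  ids <- node_ids(stree)
  fam_ids <- unique(events$family)
  bnum <- match(events$branch, ids)
  if (anyNA(bnum)) {
    stop("event map references unknown branches: ",
         paste(unique(events$branch[is.na(bnum)]), collapse = ", "))
  }
  net <- matrix(0L, nrow = length(ids), ncol = length(fam_ids),
                dimnames = list(ids, fam_ids))
  delta <- events$gain + events$duplications - events$losses
  for (r in seq_len(nrow(events))) {
    j <- match(events$family[r], fam_ids)
    net[bnum[r], j] <- net[bnum[r], j] + delta[r]
  }
  copies <- net
  par <- parent_vector(stree)
  for (v in preorder_numbers(stree)) {
    if (par[v] != 0L) copies[v, ] <- copies[par[v], ] + net[v, ]
    neg <- copies[v, ] < 0L
    if (any(neg)) {
      stop("negative ancestral copy number at node ", ids[v], " for family ",
           paste(fam_ids[neg], collapse = ", "), "; event map inconsistent")
    }
  }
  copies
}

#' Summarize curated families by origin epoch and origin-node duplications
#'
#' Computes, for a set of families, the counts and percentages used to
#' characterize a curated gene set: how many families predate the designated
#' origin nodes, originated in them, or arose after them; how many show at
#' least one duplication on an origin branch; and how many are origin-born
#' and subsequently conserved (at least one copy in at least
#' `conservation_threshold` of the designated filamentous taxa).
#'
#' @param events An `event_map`.
#' @param classification Output of [classify_branches()].
#' @param stree Species tree (`phylo`).
#' @param filamentous_taxa Leaf labels counted by the conservation rule.
#' @param conservation_threshold Minimum carrier fraction (default 0.7).
#' @return Data frame with one row per summary quantity (`n`, `percent`,
#'   computed over the total family count).
#' @export
curated_family_summary <- function(events, classification, stree,
                                   filamentous_taxa,
                                   conservation_threshold = 0.7) {
  origins <- event_map_origins(events)
  n_fam <- length(origins)
  branch_class <- stats::setNames(classification$class, classification$branch)
  root_id <- node_ids(stree)[root_number(stree)]
  branch_class[root_id] <- "PRE_ORIGIN"   # root pseudo-branch sits above all origins
  ocl <- branch_class[origins]
  bcz_dup <- with(as.data.frame(events),
                  tapply(duplications * (branch_class[branch] == "ORIGIN"),
                         family, sum))[names(origins)]
  copies <- ancestral_copy_numbers(events, stree)
  cons <- conservation_filter(copies, filamentous_taxa,
                              conservation_threshold)[names(origins)]
  n <- c(
    total = n_fam,
    pre_origin = sum(ocl %in% c("PRE_ORIGIN", "EXCLUDED")),
    origin_born = sum(ocl == "ORIGIN"),
    post_origin = sum(!ocl %in% c("PRE_ORIGIN", "EXCLUDED", "ORIGIN")),
    origin_duplicated = sum(bcz_dup > 0),
    origin_born_conserved = sum(ocl == "ORIGIN" & cons)
  )
  data.frame(
    quantity = names(n),
    n = as.integer(n),
    percent = round(100 * as.integer(n) / n_fam, 1),
    stringsAsFactors = FALSE
  )
}

#' Write an event map to TSV
#'
#' @param events An `event_map`.
#' @param path Output file path.
#' @export
write_event_map <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
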