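#' Two-sided Fisher exact test for a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test()] that adds the degenerate-margin
#' convention and a continuity-corrected odds ratio for reporting. The
#' two-sided p-value is the sum of hypergeometric probabilities (margins
#' fixed) of all tables at most as probable as the observed one. A zero row
#' or column margin makes the association untestable; such tables return
#' `p = 1` with a degenerate flag.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `p`, `odds_ratio` (0.5-continuity-corrected, for
#'   reporting only), `direction` (`"ENRICHED"`, `"DEPLETED"` or `"NONE"`)
#'   and `degenerate`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  or <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
        ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = 1, odds_ratio = or, direction = "NONE",
                degenerate = TRUE))
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  p <- min(p, 1)
  direction <- if (or > 1) "ENRICHED" else if (or < 1) "DEPLETED" else "NONE"
  list(p = p, odds_ratio = or, direction = direction, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control via [stats::p.adjust()]. `NA` entries
#' are preserved and do not count toward the number of tests.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted values (q-values), capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Duplication enrichment on origin branches per family or category
#'
#' For every tested unit (gene family or functional category) the number of
#' duplications mapped to ORIGIN ("BCZ") branches is compared with the number
#' mapped elsewhere, against the genome-wide background with the unit itself
#' subtracted. Each unit yields the 2x2 table
#' `[[unit in-origin, unit elsewhere], [background in-origin, background
#' elsewhere]]`; a two-sided Fisher exact p-value and a BH-adjusted q across
#' the battery are reported. Duplications on excluded (outgroup) branches are
#' never counted.
#'
#' @param events An `event_map` covering both the tested units and the
#'   background.
#' @param classification Output of [classify_branches()].
#' @param units Named list: unit name -> character vector of family ids. The
#'   default tests every family separately.
#' @param include_terminal Count duplications on terminal branches in the
#'   "elsewhere" total (default TRUE: the reference is the whole tree minus
#'   the excluded clade).
#' @return Data frame with columns `unit`, `a`, `b`, `c`, `d`, `p`, `q`,
#'   `odds_ratio`, `direction`, `note`. Units with zero duplications are
#'   reported as `NA` with a note.
#' @export
bcz_duplication_enrichment <- function(events, classification, units = NULL,
                                       include_terminal = TRUE) {
  ev <- as.data.frame(events)
  branch_class <- stats::setNames(classification$class, classification$branch)
  cls <- branch_class[ev$branch]
  cls[is.na(cls)] <- "PRE_ORIGIN"   # root pseudo-branch
  keep_cls <- c("PRE_ORIGIN", "ORIGIN", "POST_ORIGIN",
                if (include_terminal) "TERMINAL")
  ev <- ev[cls %in% keep_cls, , drop = FALSE]
  cls <- cls[cls %in% keep_cls]
  in_origin <- cls == "ORIGIN"
  fam_in <- tapply(ev$duplications * in_origin, ev$family, sum)
  fam_out <- tapply(ev$duplications * !in_origin, ev$family, sum)
  if (is.null(units)) {
    units <- stats::setNames(as.list(names(fam_in)), names(fam_in))
  }
  tot_in <- sum(fam_in); tot_out <- sum(fam_out)
  res <- lapply(names(units), function(u) {
    fams <- intersect(units[[u]], names(fam_in))
    a <- sum(fam_in[fams]); b <- sum(fam_out[fams])
    cc <- tot_in - a; dd <- tot_out - b
    if (a + b == 0) {
      return(data.frame(unit = u, a = a, b = b, c = cc, d = dd,
                        p = NA_real_, odds_ratio = NA_real_,
                        direction = NA_character_,
                        note = "no duplications in unit",
                        stringsAsFactors = FALSE))
    }
    ft <- fisher_exact_2x2(matrix(c(a, cc, b, dd), 2))
    data.frame(unit = u, a = a, b = b, c = cc, d = dd, p = ft$p,
               odds_ratio = ft$odds_ratio, direction = ft$direction,
               note = if (ft$degenerate) "degenerate margin" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out[, c("unit", "a", "b", "c", "d", "p", "q", "odds_ratio", "direction",
          "note")]
}

#' Loss depletion and retention in secondarily simplified clades
#'
#' For each (clade x functional category) pair, compares the number of gene
#' copies lost inside the clade with the genome-wide loss rate, relative to
#' the ancestral copy number at the node preceding the clade's stem. Two
#' retention summaries are reported: `percent_lost` uses ancestral minus
#' losses, while `percent_retained_extant` compares the mean extant copy
#' number over the clade's leaves with the ancestral count (the two differ
#' when duplications occur inside the clade).
#'
#' @param events An `event_map`.
#' @param copy_matrix Output of [ancestral_copy_numbers()].
#' @param stree Species tree (`phylo`).
#' @param clades Named character vector: clade name -> stem node identifier
#'   (the clade's root node; its subtending branch is counted as part of the
#'   clade).
#' @param categories Named list: category name -> family ids. A `genome_wide`
#'   background is computed from all families in the event map.
#' @return Data frame with one row per clade x category.
#' @export
yeast_loss_depletion <- function(events, copy_matrix, stree, clades,
                                 categories) {
  stree <- validate_species_tree(stree, assert_root = TRUE)
  ids <- node_ids(stree)
  par <- parent_vector(stree)
  ev <- as.data.frame(events)
  all_fams <- unique(ev$family)
  rows <- list()
  for (cl in names(clades)) {
    stem <- node_number(stree, clades[[cl]])
    if (stem <= ape::Ntip(stree)) stop("clade stem must be an internal node: ", cl)
    anc_node <- if (par[stem] == 0L) stem else par[stem]
    clade_branches <- ids[c(stem, descendant_numbers(stree, stem))]
    clade_tips <- intersect(clade_branches, stree$tip.label)
    in_clade <- ev$branch %in% clade_branches
    loss_by_fam <- tapply(ev$losses * in_clade, ev$family, sum)
    anc_by_fam <- copy_matrix[ids[anc_node], ]
    gw_anc <- sum(anc_by_fam[all_fams])
    gw_loss <- sum(loss_by_fam[all_fams])
    for (cat in names(categories)) {
      fams <- intersect(categories[[cat]], all_fams)
      anc <- sum(anc_by_fam[fams])
      if (anc == 0) {
        warning("category ", cat, " has zero ancestral copies before clade ",
                cl, "; skipped")
        next
      }
      losses <- sum(loss_by_fam[fams])
      bg_anc <- gw_anc - anc
      bg_loss <- gw_loss - losses
      ft <- fisher_exact_2x2(matrix(c(losses, bg_loss,
                                      anc - losses, bg_anc - bg_loss), 2))
      extant_mean <- mean(rowSums(copy_matrix[clade_tips, fams, drop = FALSE]))
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, category = cat,
        ancestral = anc, losses = losses,
        percent_lost = 100 * losses / anc,
        percent_retained = 100 * (anc - losses) / anc,
        percent_retained_extant = 100 * extant_mean / anc,
        p = ft$p, direction = ft$direction,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out
}
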