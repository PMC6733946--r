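#' Extract gene/CDS/intron structures from a GFF3 annotation
#'
#' Reads a GFF3 file (1-based inclusive coordinates) and derives, for the
#' longest mRNA of every gene, the gene length, total CDS length and the
#' intron coordinates: intron *i* spans from one past the end of CDS segment
#' *i* to one before the start of segment *i + 1* in genomic order. UTRs are
#' ignored; introns exist only between CDS segments. For minus-strand genes
#' the genomic intron coordinates are unchanged and the transcript-order
#' index runs against the genomic order.
#'
#' @param path Path to a GFF3 file with `gene`, `mRNA` and `CDS` features
#'   linked through `Parent` attributes.
#' @param species Optional species label copied into the output.
#' @return List of two data frames: `genes` (`gene`, `mrna`, `species`,
#'   `strand`, `gene_length`, `cds_length`, `n_cds`, `n_introns`,
#'   `total_intron_length`) and `introns` (`gene`, `order` in transcript
#'   direction, `start`, `end`, `length`).
#' @export
extract_gene_structures <- function(path, species = NA_character_) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  type <- as.character(df$type)
  ids <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA, nrow(df))
  parents <- if ("Parent" %in% names(df)) df$Parent else
    replicate(nrow(df), character(0), simplify = FALSE)

  genes <- df[type == "gene", , drop = FALSE]
  gene_ids <- ids[type == "gene"]
  mrna_idx <- which(type == "mRNA")
  cds_idx <- which(type == "CDS")

  mrna_parent <- vapply(parents[mrna_idx], function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  mrna_ids <- ids[mrna_idx]
  mrna_span <- df$end[mrna_idx] - df$start[mrna_idx] + 1L

  # choose the longest mRNA per gene, ties broken by smallest mRNA id
  ord <- order(mrna_parent, -mrna_span, mrna_ids)
  keep <- !duplicated(mrna_parent[ord])
  chosen <- data.frame(gene = mrna_parent[ord][keep],
                       mrna = mrna_ids[ord][keep],
                       stringsAsFactors = FALSE)

  gene_rows <- list(); intron_rows <- list()
  for (r in seq_len(nrow(chosen))) {
    g <- chosen$gene[r]; m <- chosen$mrna[r]
    ci <- cds_idx[vapply(parents[cds_idx], function(p) m %in% as.character(p),
                         logical(1))]
    if (length(ci) == 0L) {
      warning("mRNA ", m, " has no CDS segments; skipped")
      next
    }
    st <- df$start[ci]; en <- df$end[ci]
    o <- order(st)
    st <- st[o]; en <- en[o]
    if (length(st) > 1L && any(st[-1L] <= en[-length(en)])) {
      stop("overlapping CDS segments in mRNA ", m)
    }
    gi <- match(g, gene_ids)
    if (is.na(gi)) {
      warning("mRNA ", m, " has no gene parent record; skipped")
      next
    }
    strand <- as.character(genes$strand[gi])
    glen <- genes$end[gi] - genes$start[gi] + 1L
    n_cds <- length(st)
    if (n_cds > 1L) {
      istart <- en[-n_cds] + 1L
      iend <- st[-1L] - 1L
      ilen <- iend - istart + 1L
      ord_tx <- if (strand == "-") rev(seq_len(n_cds - 1L)) else
        seq_len(n_cds - 1L)
      intron_rows[[length(intron_rows) + 1L]] <- data.frame(
        gene = g, order = ord_tx, start = istart, end = iend, length = ilen,
        stringsAsFactors = FALSE)
    }
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene = g, mrna = m, species = species, strand = strand,
      gene_length = glen, cds_length = sum(en - st + 1L), n_cds = n_cds,
      n_introns = n_cds - 1L,
      total_intron_length = if (n_cds > 1L) sum(st[-1L] - en[-n_cds] - 1L) else 0L,
      stringsAsFactors = FALSE)
  }
  # CDS records pointing at no chosen mRNA and no mRNA at all
  orphan <- cds_idx[lengths(parents[cds_idx]) == 0L]
  if (length(orphan)) warning(length(orphan), " CDS record(s) without Parent skipped")
  list(genes = do.call(rbind, gene_rows),
       introns = do.call(rbind, intron_rows))
}

#' Welch's two-sample t-test
#'
#' Unpooled-variance two-sided t-test with Welch-Satterthwaite degrees of
#' freedom, via [stats::t.test()] with `var.equal = FALSE`. Two constant
#' groups with equal means return `t = 0, p = 1`; constant groups with
#' different means return an infinite statistic with `p = 0` and a
#' degenerate flag.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2,
                  p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2,
                p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Gene-structure contrasts between cellularity groups
#'
#' Welch contrasts of gene length, CDS length and intron length between two
#' groups of species (typically plesiomorphically unicellular vs
#' multicellular).
#'
#' @param structures_a,structures_b Outputs of [extract_gene_structures()]
#'   (or row-bound `genes`/`introns` tables) for the two groups.
#' @return Data frame with one row per statistic (`gene_length`,
#'   `cds_length`, `intron_length`): group means, `t`, `df`, `p`.
#' @export
gene_structure_contrasts <- function(structures_a, structures_b) {
  pull <- function(s, what) {
    if (what == "intron_length") return(s$introns$length)
    s$genes[[what]]
  }
  stats_ <- c("gene_length", "cds_length", "intron_length")
  rows <- lapply(stats_, function(w) {
    a <- pull(structures_a, w); b <- pull(structures_b, w)
    wt <- welch_t_test(a, b)
    data.frame(statistic = w, mean_a = mean(a), mean_b = mean(b),
               t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Domain-architecture inventory with a conservation rule
#'
#' Tabulates ordered domain architectures per gene family and cellularity
#' group. An architecture is retained when it occurs in at least
#' `conservation_threshold` of the group's species that carry the family;
#' order matters, so `A>B` and `B>A` are distinct architectures. A family is
#' flagged as showing an architecture change when some retained architecture
#' is present in one group and entirely absent from the other.
#'
#' @param arch Data frame with columns `protein`, `species`, `group`,
#'   `family`, `architecture` (domains joined by `>` in protein order).
#' @param conservation_threshold Minimum within-group species fraction
#'   (default 0.7).
#' @return List with `inventory` (per family x group x architecture:
#'   `n_species`, `frac_species`, `retained`) and `changes` (per family:
#'   logical `changed`).
#' @export
architecture_inventory <- function(arch, conservation_threshold = 0.7) {
  stopifnot(all(c("protein", "species", "group", "family", "architecture")
                %in% names(arch)))
  arch <- arch[nzchar(arch$architecture), , drop = FALSE]
  rows <- list()
  for (f in unique(arch$family)) {
    sub <- arch[arch$family == f, , drop = FALSE]
    if (nrow(sub) == 0L) { warning("family ", f, " has no annotated proteins"); next }
    for (g in unique(sub$group)) {
      sg <- sub[sub$group == g, , drop = FALSE]
      n_sp <- length(unique(sg$species))
      tab <- tapply(sg$species, sg$architecture,
                    function(s) length(unique(s)))
      rows[[length(rows) + 1L]] <- data.frame(
        family = f, group = g, architecture = names(tab),
        n_species = as.integer(tab),
        frac_species = as.numeric(tab) / n_sp,
        stringsAsFactors = FALSE)
    }
  }
  inv <- do.call(rbind, rows)
  rownames(inv) <- NULL
  inv$retained <- inv$frac_species >= conservation_threshold
  changes <- do.call(rbind, lapply(split(inv, inv$family), function(d) {
    groups <- unique(d$group)
    changed <- FALSE
    if (length(groups) == 2L) {
      for (g in groups) {
        ret <- d$architecture[d$group == g & d$retained]
        other <- d$architecture[d$group != g]
        if (any(!ret %in% other)) changed <- TRUE
      }
    }
    data.frame(family = d$family[1L], changed = changed,
               stringsAsFactors = FALSE)
  }))
  rownames(changes) <- NULL
  list(inventory = inv, changes = changes)
}

#' Per-family domain-count regression between groups
#'
#' Poisson regression (log link) of the per-protein domain count on the
#' cellularity group, with a likelihood-ratio p-value against the
#' intercept-only model. A positive coefficient means more domains in the
#' `multicellular` group. Families with constant counts are reported as
#' degenerate with `p = 1` rather than failing, and a Pearson dispersion
#' diagnostic is attached.
#'
#' @param domains Data frame with columns `protein`, `group` (values
#'   `unicellular`/`multicellular`), `family`, `n_domains`.
#' @return Data frame per family: `coefficient` (log rate ratio,
#'   multicellular vs unicellular), `p`, `dispersion`, `degenerate`.
#' @export
domain_count_glm <- function(domains) {
  stopifnot(all(c("protein", "group", "family", "n_domains")
                %in% names(domains)))
  rows <- list()
  for (f in unique(domains$family)) {
    sub <- domains[domains$family == f, , drop = FALSE]
    if (length(unique(sub$group)) < 2L ||
        any(table(sub$group) < 2L)) next
    grp <- factor(sub$group, levels = c("unicellular", "multicellular"))
    y <- sub$n_domains
    if (stats::var(y) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        family = f, coefficient = 0, p = 1, dispersion = NA_real_,
        degenerate = TRUE, stringsAsFactors = FALSE)
      next
    }
    fit1 <- suppressWarnings(stats::glm(y ~ grp, family = stats::poisson()))
    fit0 <- suppressWarnings(stats::glm(y ~ 1, family = stats::poisson()))
    lrt <- fit0$deviance - fit1$deviance
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    disp <- sum(stats::residuals(fit1, type = "pearson")^2) / fit1$df.residual
    rows[[length(rows) + 1L]] <- data.frame(
      family = f, coefficient = unname(stats::coef(fit1)[2L]), p = p,
      dispersion = disp, degenerate = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
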