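# Shared fixtures and independent oracles. Every oracle here recomputes the
# target quantity by a route disjoint from the package implementation.

# 4-tip in-group + 2-tip outgroup tree used across modules
fixture_tree <- function() {
  parse_newick(
    "((((A:1,B:1)AB:1,C:1)ABC:1,D:1)ABCD:1,(X:1,Y:1)OUT:1)R;")
}

# 8-tip tree with PRE / three ORIGIN / POST structure
fixture_screen_tree <- function() {
  parse_newick(paste0(
    "((((((a:0.2,b:0.3)Q1:0.25,(g:0.2,h:0.35)Q2:0.3)O3:0.2,c:0.2)O2:0.3,",
    "d:0.25)O1:0.2,e:0.3)P1:0.4,f:0.3)R;"))
}

fixture_screen_classification <- function(tree = fixture_screen_tree()) {
  classify_branches(tree, origin_nodes = c("O1", "O2", "O3"))
}

# ---- oracles ---------------------------------------------------------------

# two-sided Fisher p by exhaustive enumeration over tables with the observed
# margins (hypergeometric probabilities; same relative-error tie rule as the
# classical definition)
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  a <- lo:hi
  probs <- stats::dhyper(a, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# independent BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Welch statistic from first principles
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# classical one-way F via R's linear-model ANOVA
oracle_oneway_f <- function(x, g) {
  unname(anova(lm(x ~ factor(g)))[["F value"]][1])
}

# Dollo minimal losses by brute force: try every loss-branch subset under the
# carrier MRCA and keep the smallest one whose replay matches the presence
# pattern
oracle_dollo_losses <- function(presence, tree) {
  carriers <- names(presence)[presence > 0]
  origin <- mrca_node(tree, carriers)
  ids <- node_ids(tree)
  onum <- match(origin, ids)
  # leaves and their root-to-leaf node paths (via ape, independent of the
  # package's traversal helpers)
  below <- if (onum <= ape::Ntip(tree)) onum else
    c(onum, phangorn::Descendants(tree, onum, "all"))
  branches <- setdiff(below, onum)
  paths <- lapply(seq_len(ape::Ntip(tree)), function(tip) {
    if (!(tip %in% below)) return(NULL)
    if (tip == onum) integer(0) else ape::nodepath(tree, onum, tip)[-1]
  })
  target <- unname(presence[tree$tip.label] > 0)
  best <- NULL
  for (k in 0:length(branches)) {
    for (s in utils::combn(branches, k, simplify = FALSE)) {
      present <- vapply(paths, function(p) !is.null(p) && !any(p %in% s),
                        logical(1))
      if (identical(present, target)) { best <- s; break }
    }
    if (!is.null(best)) break
  }
  length(best)
}

# Independent reconciliation oracle: MRCA mappings and duplication flags via
# ape/phangorn utilities, total losses from the per-edge path-distance
# formula with distances measured by ape::nodepath.
oracle_reconcile <- function(gtree, stree, species) {
  ntip_g <- ape::Ntip(gtree)
  nn_g <- ntip_g + gtree$Nnode
  sp_of <- function(v) {
    tips <- if (v <= ntip_g) v else phangorn::Descendants(gtree, v, "tips")[[1]]
    unique(unname(species[gtree$tip.label[tips]]))
  }
  map <- integer(nn_g)
  for (v in seq_len(nn_g)) {
    spl <- sp_of(v)
    map[v] <- if (length(spl) == 1L) match(spl, stree$tip.label) else
      ape::getMRCA(stree, spl)
  }
  is_dup <- rep(FALSE, nn_g)
  for (v in (ntip_g + 1L):nn_g) {
    kids <- gtree$edge[gtree$edge[, 1] == v, 2]
    is_dup[v] <- any(map[kids] == map[v])
  }
  total_losses <- 0L
  for (e in seq_len(nrow(gtree$edge))) {
    g <- gtree$edge[e, 1]; c_ <- gtree$edge[e, 2]
    if (map[g] == map[c_]) next
    d <- length(ape::nodepath(stree, map[g], map[c_])) - 1L
    total_losses <- total_losses + d - 1L + as.integer(is_dup[g])
  }
  list(map = map, is_dup = is_dup, n_dup = sum(is_dup),
       total_losses = total_losses)
}

# quadrature oracle for the balanced 4-tip tree ((A,B)U,(C,D)V)R with unit
# branches; tip signs +1 hyphal, -1 non-hyphal, 0 uncertain
oracle_threshold_pp <- function(sA, sB, sC, sD, step = 0.02, lim = 9) {
  x <- seq(-lim, lim, by = step)
  M <- dnorm(outer(x, x, "-"))
  tf <- function(s) if (s == 0) rep(1, length(x)) else pnorm(s * x)
  fu <- tf(sA) * tf(sB)
  fv <- tf(sC) * tf(sD)
  A <- colSums(M * fu)
  B <- colSums(M * fv)
  pp_r <- sum((A * B)[x > 0]) / sum(A * B)
  Ju <- (M * fu) %*% B
  Jv <- (M * fv) %*% A
  c(R = pp_r,
    U = sum(Ju[x > 0]) / sum(Ju),
    V = sum(Jv[x > 0]) / sum(Jv))
}

# random rooted binary gene tree over a species set, with per-gene species
random_gene_tree <- function(stree, n_genes, seed) {
  set.seed(seed)
  sp <- sample(stree$tip.label, n_genes, replace = TRUE)
  genes <- paste0("g", seq_len(n_genes), "_", sp)
  tr <- ape::rtree(n_genes, rooted = TRUE, tip.label = genes, br = NULL)
  list(tree = tr, species = stats::setNames(sp, genes))
}
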