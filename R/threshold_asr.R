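#' Threshold-model ancestral state reconstruction by Bayesian MCMC
#'
#' Reconstructs the posterior probability of a binary trait (hyphal vs
#' non-hyphal) at every internal node of a species tree under the threshold
#' model: the observed state is the sign of a continuous latent liability
#' evolving by Brownian motion along the tree. Liabilities at all nodes are
#' sampled by Gibbs updates from their full conditionals (normal, with mean
#' and precision given by the neighboring nodes weighted by inverse branch
#' lengths); tip liabilities are truncated to the half-line matching the
#' observed state, tips coded `uncertain` are unconstrained, the threshold is
#' fixed at 0 and the Brownian rate at 1 (both are unidentifiable for a
#' binary trait and serve only to set the liability scale). The root receives
#' an improper flat prior, realized through its Gibbs conditional on its
#' children.
#'
#' @param tree Species tree (`phylo`) with strictly positive branch lengths
#'   on all edges used.
#' @param traits Named character vector species -> state, states in
#'   `c("hyphal", "non_hyphal", "uncertain")`. Every tip needs an entry.
#' @param generations Number of MCMC generations (default 1e5; each
#'   generation sweeps all nodes once).
#' @param burnin_fraction Fraction of generations discarded (default 0.2).
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @return An object of class `asr_result`: data frame `pp` with columns
#'   `node`, `pp_hyphal`, `pp_nonhyphal` (internal nodes, ape order), the
#'   per-generation log-density `trace`, and the chain settings.
#' @export
ancthresh_mcmc <- function(tree, traits, generations = 1e5,
                           burnin_fraction = 0.2, seed = 1L) {
  tree <- validate_species_tree(tree, assert_root = TRUE)
  if (generations < 1000) stop("generations must be at least 1000")
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must lie in [0, 1)")
  }
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  states <- traits[tree$tip.label]
  if (anyNA(states)) {
    stop("missing trait entries for: ",
         paste(tree$tip.label[is.na(states)], collapse = ", "))
  }
  if (!all(states %in% c("hyphal", "non_hyphal", "uncertain"))) {
    stop("states must be 'hyphal', 'non_hyphal' or 'uncertain'")
  }
  if (!any(states == "hyphal") || !any(states == "non_hyphal")) {
    warning("fewer than one tip per determinate state; posterior driven by the prior")
  }

  # neighbor structure: for node v, neighbors nb[[v]] with weights 1/branch
  par <- parent_vector(tree)
  blen <- numeric(nnode)
  blen[tree$edge[, 2L]] <- tree$edge.length
  constrained <- which(states != "uncertain")
  if (any(blen[constrained] <= 0)) {
    stop("zero-length branch incident to a constrained tip: ",
         paste(tree$tip.label[constrained][blen[constrained] <= 0],
               collapse = ", "))
  }
  if (any(blen[-root_number(tree)] <= 0)) {
    stop("all branch lengths must be strictly positive for the Gibbs sweep")
  }
  nb <- vector("list", nnode)
  wt <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1L]; b <- tree$edge[i, 2L]; w <- 1 / tree$edge.length[i]
    nb[[a]] <- c(nb[[a]], b); wt[[a]] <- c(wt[[a]], w)
    nb[[b]] <- c(nb[[b]], a); wt[[b]] <- c(wt[[b]], w)
  }
  wsum <- vapply(wt, sum, numeric(1))

  set.seed(seed)
  liab <- numeric(nnode)
  liab[seq_len(ntip)] <- ifelse(states == "hyphal", 1,
                         ifelse(states == "non_hyphal", -1, 0))
  internal <- (ntip + 1L):nnode
  hy_count <- numeric(length(internal))
  trace <- numeric(generations)
  burn <- floor(burnin_fraction * generations)
  lo <- ifelse(states == "hyphal", 0, -Inf)
  hi <- ifelse(states == "non_hyphal", 0, Inf)

  edge_child <- tree$edge[, 2L]
  edge_par <- tree$edge[, 1L]
  inv_len <- 1 / tree$edge.length
  sweep_order <- c(internal, seq_len(ntip))

  for (g in seq_len(generations)) {
    for (v in sweep_order) {
      m <- sum(wt[[v]] * liab[nb[[v]]]) / wsum[v]
      s <- sqrt(1 / wsum[v])
      if (v <= ntip && states[v] != "uncertain") {
        liab[v] <- rtruncnorm1(m, s, lo[v], hi[v])
      } else {
        liab[v] <- stats::rnorm(1L, m, s)
      }
    }
    d <- liab[edge_child] - liab[edge_par]
    trace[g] <- -0.5 * sum(d * d * inv_len) -
      0.5 * sum(log(tree$edge.length))
    if (g > burn) hy_count <- hy_count + (liab[internal] > 0)
  }
  n_kept <- generations - burn
  pp <- hy_count / n_kept
  structure(list(
    pp = data.frame(node = node_ids(tree)[internal],
                    pp_hyphal = pp, pp_nonhyphal = 1 - pp,
                    stringsAsFactors = FALSE),
    trace = trace,
    settings = list(generations = generations,
                    burnin_fraction = burnin_fraction, seed = seed,
                    kept = n_kept)
  ), class = "asr_result")
}

# one draw from N(mean, sd) truncated to (lo, hi) by inverse-CDF; falls back
# to the untruncated draw when the interval mass underflows
rtruncnorm1 <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) {
    # deep tail: return the nearer boundary nudged inward
    return(if (is.finite(lo)) lo + 1e-8 * sd else hi - 1e-8 * sd)
  }
  stats::qnorm(stats::runif(1L, plo, phi), mean, sd)
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Threshold-model ASR:", nrow(x$pp), "internal nodes,",
      x$settings$generations, "generations (burn-in",
      format(100 * x$settings$burnin_fraction), "%)\n")
  print(utils::head(x$pp, 10), row.names = FALSE)
  invisible(x)
}

#' Write ASR posterior probabilities to TSV
#'
#' @param asr An `asr_result`.
#' @param path Output file path.
#' @export
write_asr <- function(asr, path) {
  utils::write.table(asr$pp, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
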