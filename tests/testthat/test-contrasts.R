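test_that("Fisher p matches hand-enumerable tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  # margins (2,2)/(2,2): three tables, observed the most extreme
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3,
               tolerance = 1e-12)
  deg <- fisher_exact_2x2(matrix(c(0, 0, 10, 10), 2))
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
})

test_that("Fisher p equals exhaustive enumeration over all small margins", {
  set.seed(4)
  n_checked <- 0
  for (i in 1:400) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(tab) > 60 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(t(tab))$p, fisher_exact_2x2(tab)$p,
                 tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})

test_that("BH adjustment equals an independent step-up and dominates raw p", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
    # BH rejections contain Bonferroni rejections
    alpha <- 0.1
    expect_true(all(which(p <= alpha / length(p)) %in% which(q <= alpha)))
  }
})

test_that("origin-branch duplication enrichment flags a concentrated unit", {
  tr <- fixture_screen_tree()
  cls <- fixture_screen_classification(tr)
  set.seed(2)
  bg <- simulate_poisson_dup_families(tr, cls, 120, dup_rate = 3, seed = 7)
  # focal family with all 20 duplications on ORIGIN branches
  focal <- structure(data.frame(
    family = "focal", branch = c("R", "O1", "O2"),
    gain = c(1L, 0L, 0L), duplications = c(0L, 12L, 8L), losses = 0L),
    origins = c(focal = "R"), class = c("event_map", "data.frame"))
  em <- combine_event_maps(bg, focal)
  res <- bcz_duplication_enrichment(em, cls)
  row <- res[res$unit == "focal", ]
  expect_lt(row$p, 0.001)
  expect_equal(row$direction, "ENRICHED")
  expect_equal(row$a, 20)
  # direct hypergeometric cross-check of the focal table
  expect_equal(row$p, oracle_fisher_p(matrix(c(row$a, row$c, row$b, row$d),
                                             2)), tolerance = 1e-9)
  # a family with zero duplications is NA with a reason
  solo <- structure(data.frame(family = "empty", branch = "R", gain = 1L,
                               duplications = 0L, losses = 0L),
                    origins = c(empty = "R"),
                    class = c("event_map", "data.frame"))
  res2 <- bcz_duplication_enrichment(combine_event_maps(bg, solo), cls)
  expect_true(is.na(res2$p[res2$unit == "empty"]))
})

test_that("null units reject at close to the nominal Fisher level", {
  tr <- fixture_screen_tree()
  cls <- fixture_screen_classification(tr)
  rej <- 0; n <- 400
  for (i in seq_len(n)) {
    em <- simulate_poisson_dup_families(tr, cls, 2, dup_rate = 12,
                                        seed = 5000 + i)
    res <- bcz_duplication_enrichment(em, cls,
                                      units = list(u = "null0001"))
    if (!is.na(res$p[1]) && res$p[1] < 0.05) rej <- rej + 1
  }
  # Fisher is conservative on discrete tables: rate must not exceed alpha
  # by more than binomial noise, and should not collapse to zero
  expect_lt(rej / n, 0.05 + 2 * sqrt(0.05 * 0.95 / n))
  expect_gt(rej / n, 0)
})

test_that("yeast-clade loss report computes retention arithmetic", {
  tr <- fixture_screen_tree()
  # families: 100 copies ancestral to Q1 clade (gain at root + dups on P1/O*),
  # 35 lost inside the clade
  fams <- sprintf("f%03d", 1:100)
  rows <- list()
  for (i in seq_along(fams)) {
    loses <- i <= 35
    rows[[i]] <- data.frame(
      family = fams[i],
      branch = c("R", if (loses) "a"),
      gain = c(1L, if (loses) 0L),
      duplications = 0L,
      losses = c(0L, if (loses) 1L))
  }
  em <- structure(do.call(rbind, rows),
                  origins = stats::setNames(rep("R", 100), fams),
                  class = c("event_map", "data.frame"))
  cm <- ancestral_copy_numbers(em, tr)
  rep_ <- yeast_loss_depletion(em, cm, tr, clades = c(yeastQ1 = "Q1"),
                               categories = list(all = fams))
  expect_equal(rep_$ancestral, 100)
  expect_equal(rep_$losses, 35)
  expect_equal(rep_$percent_lost, 35)
  expect_equal(rep_$percent_retained, 65)
  # extant retention: a lost in 35 families, b in none -> mean copies 82.5
  expect_equal(rep_$percent_retained_extant, 82.5)
})

test_that("a loss-free category against a lossy background is depleted", {
  tr <- fixture_screen_tree()
  mk <- function(fam, lose) data.frame(
    family = fam, branch = c("R", if (lose) "a"),
    gain = c(1L, if (lose) 0L), duplications = 0L,
    losses = c(0L, if (lose) 1L))
  fams <- sprintf("g%02d", 1:60)
  rows <- lapply(seq_along(fams), function(i) mk(fams[i], i <= 40))
  em <- structure(do.call(rbind, rows),
                  origins = stats::setNames(rep("R", 60), fams),
                  class = c("event_map", "data.frame"))
  cm <- ancestral_copy_numbers(em, tr)
  rep_ <- yeast_loss_depletion(em, cm, tr, clades = c(q = "Q1"),
                               categories = list(keepers = fams[41:60]))
  expect_equal(rep_$losses, 0)
  expect_equal(rep_$direction, "DEPLETED")
})
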