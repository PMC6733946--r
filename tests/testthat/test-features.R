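write_mini_gff <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("CDS and intron arithmetic follows the inclusive convention", {
  path <- write_mini_gff(c(
    "chr1\tx\tgene\t100\t400\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t100\t400\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tx\tCDS\t100\t200\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\tx\tCDS\t301\t400\t.\t+\t0\tID=c2;Parent=m1"))
  gs <- extract_gene_structures(path)
  expect_equal(gs$genes$cds_length, 201L)
  expect_equal(gs$genes$n_introns, 1L)
  expect_equal(gs$introns$start, 201L)
  expect_equal(gs$introns$end, 300L)
  expect_equal(gs$introns$length, 100L)
  expect_equal(gs$genes$gene_length, 301L)
})

test_that("single-CDS genes and minus-strand transcript order", {
  path <- write_mini_gff(c(
    "chr1\tx\tgene\t10\t90\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t10\t90\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tx\tCDS\t10\t90\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\tx\tgene\t100\t400\t.\t-\t.\tID=g2",
    "chr1\tx\tmRNA\t100\t400\t.\t-\t.\tID=m2;Parent=g2",
    "chr1\tx\tCDS\t100\t150\t.\t-\t0\tID=c2;Parent=m2",
    "chr1\tx\tCDS\t200\t250\t.\t-\t0\tID=c3;Parent=m2",
    "chr1\tx\tCDS\t300\t400\t.\t-\t0\tID=c4;Parent=m2"))
  gs <- extract_gene_structures(path)
  g1 <- gs$genes[gs$genes$gene == "g1", ]
  expect_equal(g1$n_introns, 0L)
  i2 <- gs$introns[gs$introns$gene == "g2", ]
  # genomic coordinates unchanged; transcript order reversed on minus strand
  expect_equal(i2$start, c(151L, 251L))
  expect_equal(i2$order, c(2L, 1L))
})

test_that("overlapping CDS segments are an error and the longest mRNA wins", {
  bad <- write_mini_gff(c(
    "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t100\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tx\tCDS\t1\t50\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\tx\tCDS\t40\t100\t.\t+\t0\tID=c2;Parent=m1"))
  expect_error(extract_gene_structures(bad), "overlapping")
  iso <- write_mini_gff(c(
    "chr1\tx\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t100\t.\t+\t.\tID=mShort;Parent=g1",
    "chr1\tx\tCDS\t1\t100\t.\t+\t0\tID=c1;Parent=mShort",
    "chr1\tx\tmRNA\t1\t300\t.\t+\t.\tID=mLong;Parent=g1",
    "chr1\tx\tCDS\t1\t300\t.\t+\t0\tID=c2;Parent=mLong"))
  gs <- extract_gene_structures(iso)
  expect_equal(gs$genes$mrna, "mLong")
})

test_that("Welch test equals the closed-form statistic", {
  res <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4, tolerance = 1e-6)
  expect_equal(res$p, 0.2878641, tolerance = 1e-6)
  set.seed(8)
  for (i in 1:15) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    got <- welch_t_test(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  same <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("round trip through the feature generator is exact", {
  sim <- simulate_features(sim_feature_config(), n_genes = 40, seed = 3,
                           dir = tempfile("ft"))
  for (grp in names(sim$gff)) {
    gs <- extract_gene_structures(sim$gff[[grp]])
    truth <- sim$truth[sim$truth$group == grp, ]
    m <- match(truth$gene, gs$genes$gene)
    expect_false(anyNA(m))
    expect_equal(gs$genes$cds_length[m], truth$cds_length)
    expect_equal(gs$genes$gene_length[m], truth$gene_length)
    expect_equal(gs$genes$total_intron_length[m], truth$total_intron_length)
    expect_equal(gs$genes$n_cds[m], truth$n_cds)
  }
})

test_that("simulated group shifts are recovered by the Welch contrasts", {
  sim <- simulate_features(sim_feature_config(), n_genes = 120, seed = 5,
                           dir = tempfile("ft"))
  uni <- extract_gene_structures(sim$gff[["unicellular"]])
  mul <- extract_gene_structures(sim$gff[["multicellular"]])
  res <- gene_structure_contrasts(mul, uni)
  glen <- res[res$statistic == "gene_length", ]
  expect_gt(glen$mean_a, glen$mean_b)
  expect_lt(glen$p, 0.01)
})

test_that("architecture inventory applies the order-sensitive 70% rule", {
  arch <- data.frame(
    protein = sprintf("p%02d", 1:14),
    species = c(paste0("u", 1:5), paste0("u", 1:4), paste0("m", 1:5)),
    group = c(rep("unicellular", 9), rep("multicellular", 5)),
    family = "fam1",
    architecture = c(rep("PF1>PF2", 5), rep("PF2>PF1", 4),
                     rep("PF1>PF2>PF3", 5)))
  inv <- architecture_inventory(arch, 0.7)
  u <- inv$inventory[inv$inventory$group == "unicellular", ]
  expect_setequal(u$architecture, c("PF1>PF2", "PF2>PF1"))  # order matters
  expect_true(u$retained[u$architecture == "PF1>PF2"])       # 5/5
  expect_true(u$retained[u$architecture == "PF2>PF1"])       # 4/5 = 0.8
  expect_true(inv$changes$changed[1])   # PF1>PF2>PF3 absent in unicellular
  # below-threshold architectures are dropped from retention
  arch2 <- arch
  arch2$architecture[6:9] <- "PF1>PF2"   # PF2>PF1 disappears
  arch2$architecture[1:2] <- "PF9"       # PF9 in 2/5 = 40%
  inv2 <- architecture_inventory(arch2, 0.7)
  u2 <- inv2$inventory[inv2$inventory$group == "unicellular", ]
  expect_false(u2$retained[u2$architecture == "PF9"])
})

test_that("domain-count GLM matches the direct LRT and flags constants", {
  # closed-form Poisson LRT oracle: group means are the MLEs
  oracle_poisson_lrt <- function(y, g) {
    mu_g <- ave(y, g)
    dev <- 2 * (sum(dpois(y, mu_g, log = TRUE)) -
                  sum(dpois(y, mean(y), log = TRUE)))
    pchisq(dev, df = 1, lower.tail = FALSE)
  }
  doms <- data.frame(
    protein = sprintf("p%02d", 1:20),
    group = rep(c("unicellular", "multicellular"), each = 10),
    family = "fam1",
    n_domains = rep(c(2L, 3L), each = 10))
  res <- domain_count_glm(doms)
  expect_gt(res$coefficient, 0)
  expect_equal(res$coefficient, log(3 / 2), tolerance = 1e-6)
  expect_equal(res$p, oracle_poisson_lrt(doms$n_domains, doms$group),
               tolerance = 1e-8)
  const <- doms; const$n_domains <- 2L
  resc <- domain_count_glm(const)
  expect_true(resc$degenerate)
  expect_equal(resc$p, 1)
  # power at the stated scale: baseline 2 vs 3, n = 50 per group
  set.seed(9)
  hits <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    d <- data.frame(protein = sprintf("q%03d", 1:100),
                    group = rep(c("unicellular", "multicellular"), each = 50),
                    family = "f",
                    n_domains = c(rpois(50, 2), rpois(50, 3)))
    r <- domain_count_glm(d)
    if (nrow(r) && !r$degenerate && r$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.7)
})
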