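test_that("site_level is the methylated read fraction", {
  expect_equal(site_level(3, 1), 0.75)
  expect_equal(site_level(0, 5), 0)
  expect_equal(site_level(7, 0), 1)
  expect_equal(site_level(c(3, 0), c(1, 5)), c(0.75, 0))
  expect_error(site_level(0, 0), "zero total coverage")
})

test_that("pair_samples keeps only sites jointly covered at the threshold", {
  mk <- function(rows) {
    dt <- data.table(chrom = "chr1", pos = rows$pos, strand = "+",
                     n_meth = rows$m, n_unmeth = rows$u, context = "CG")
    setorder(dt, chrom, pos, strand)
    dt
  }
  a <- mk(list(pos = c(10L, 20L), m = c(3L, 3L), u = c(2L, 0L)))
  b <- mk(list(pos = c(10L, 20L), m = c(1L, 2L), u = c(1L, 1L)))
  pair <- pair_samples(a, b, min_total_reads = 3)
  # site 10 has only 2 reads in B -> excluded; site 20 kept
  expect_equal(pair$pos, 20L)
  expect_equal(pair$level_a, 1)
  expect_equal(pair$level_b, 2 / 3)
  # disjoint site sets pair to nothing
  c2 <- mk(list(pos = 99L, m = 5L, u = 0L))
  expect_equal(nrow(pair_samples(a, c2)), 0L)
  # unsorted input is refused
  un <- a[c(2, 1)]
  expect_error(pair_samples(un, b), "sorted")
})

test_that("swapping samples permutes levels but never the site set", {
  sim <- small_sim()
  fwd <- pair_samples(sim$sample_a, sim$sample_b)
  rev <- pair_samples(sim$sample_b, sim$sample_a)
  expect_equal(rev[, .(chrom, pos, strand, context)],
               fwd[, .(chrom, pos, strand, context)])
  expect_equal(rev$level_a, fwd$level_b)
  expect_equal(rev$level_b, fwd$level_a)
})

test_that("mC calling counts covered sites with enough methylated reads", {
  s <- data.table(chrom = "chr1", pos = c(0L, 10L, 20L), strand = "+",
                  n_meth = c(3L, 0L, 1L), n_unmeth = c(1L, 4L, 9L),
                  context = "CG")
  res <- call_mcs(s)
  expect_equal(res$summary[context == "all", n_mc], 2L)
  expect_equal(res$summary[context == "CG", rate], 2 / 3)
  res2 <- call_mcs(s, min_meth_reads = 2)
  expect_equal(res2$summary[context == "all", n_mc], 1L)
  s0 <- copy(s)[, n_meth := 0L][, n_unmeth := 5L]
  res0 <- call_mcs(s0)
  expect_equal(res0$summary[context == "all", n_mc], 0L)
  expect_equal(res0$summary[context == "CG", rate], 0)
})

test_that("bin profiles tile, truncate and count as defined", {
  s <- data.table(chrom = "chr1",
                  pos = as.integer(seq(1000, 46000, length.out = 10)),
                  strand = "+", n_meth = 5L, n_unmeth = 5L,
                  context = "CHH")
  prof <- bin_profiles(s, c(chr1 = 120000), bin_size = 50000)
  expect_equal(unique(prof[, .(bin_start, bin_end)]),
               data.table(bin_start = c(0L, 50000L, 100000L),
                          bin_end = c(50000L, 100000L, 120000L)))
  first <- prof[bin_start == 0 & context == "CHH"]
  expect_equal(first$mc_density, 10 / 50000)
  expect_equal(first$mean_level, 0.5)
  emptyb <- prof[bin_start == 50000 & context == "CHH"]
  expect_equal(emptyb$mc_density, 0)
  expect_true(is.na(emptyb$mean_level))
  expect_error(bin_profiles(s, c(chr1 = 30000)), "beyond declared")
})

test_that("bin densities integrate back to total mC counts per context", {
  sim <- small_sim()
  prof <- bin_profiles(sim$sample_a, sim$config$chrom_lengths)
  mc <- call_mcs(sim$sample_a)
  for (ctx in c("CG", "CHG", "CHH")) {
    total <- prof[context == ctx, sum(mc_density * (bin_end - bin_start))]
    expect_equal(total, mc$summary[context == ctx, n_mc])
  }
})

test_that("cross-sample correlations match a direct sum-formula oracle", {
  # textbook product-moment formula, written independently of stats::cor
  r_oracle <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  set.seed(31)
  la <- runif(1000, 0.2, 0.8)
  lb <- pmin(0.999, pmax(0.001, la + rnorm(1000, 0, 0.05)))
  pair <- make_pair(la, lb)
  # counts are rounded to denominator 10; use the realised levels
  cc <- chromosome_correlations(pair, by = "level")
  r <- cc[context == "CHH", r]
  expect_equal(r, r_oracle(pair$level_a, pair$level_b), tolerance = 1e-12)
  expect_gt(r, 0.5)

  ident <- make_pair(la, la)
  expect_equal(chromosome_correlations(ident)[context == "all", r], 1)
  anti <- make_pair(la, 1 - la)
  expect_equal(chromosome_correlations(anti)[context == "all", r], -1)
})

test_that("correlation is flagged undefined for degenerate inputs", {
  flat <- make_pair(rep(0.5, 10), runif(10, 0.2, 0.8))
  expect_true(is.na(chromosome_correlations(flat)[context == "all", r]))
  tiny <- make_pair(c(0.1, 0.9), c(0.2, 0.8))
  expect_true(is.na(chromosome_correlations(tiny)[context == "all", r]))
})

test_that("divergence classifies per-site fold changes around the threshold", {
  pair <- make_pair(c(0.5, 0.5), c(0.65, 0.55))
  ds <- divergence_summary(pair)
  # 0.65/0.5 = 1.3 > 1.2 -> increased; 0.55/0.5 = 1.1 -> unchanged
  expect_equal(ds[context == "all", pct_increased], 50)
  expect_equal(ds[context == "all", pct_decreased], 0)
})

test_that("divergence percentages recover planted class fractions", {
  # 300 increased at ratio 1.5, 200 decreased at ratio 1.5, 500 unchanged
  la <- c(rep(0.4, 300), rep(0.6, 200), rep(0.4, 500))
  lb <- c(rep(0.6, 300), rep(0.4, 200), rep(0.4, 500))
  pair <- make_pair(la, lb)
  ds <- divergence_summary(pair)
  # brute-force per-site oracle
  inc <- sum(lb / la > 1.2)
  dec <- sum(la / lb > 1.2)
  expect_equal(ds[context == "all", pct_increased], 100 * inc / 1000)
  expect_equal(ds[context == "all", pct_decreased], 100 * dec / 1000)
  expect_equal(ds[context == "all", pct_increased], 30)
  expect_equal(ds[context == "all", pct_decreased], 20)
  expect_equal(ds[context == "all", pct_total_variant], 50)
})

test_that("zero-denominator sites land in the strong class of their direction", {
  pair <- make_pair(c(0, 0.6), c(0.6, 0))
  ds <- divergence_summary(pair)
  expect_equal(ds[context == "all", pct_increased_ge2fold], 50)
  expect_equal(ds[context == "all", pct_decreased_ge2fold], 50)
})

test_that("identical samples show zero divergence and unit correlations", {
  sim <- small_sim()
  self <- pair_samples(sim$sample_a, sim$sample_a)
  ds <- divergence_summary(self)
  expect_true(all(ds$pct_increased == 0))
  expect_true(all(ds$pct_decreased == 0))
  expect_true(all(ds$pct_total_variant == ds$pct_increased + ds$pct_decreased))
  cc <- chromosome_correlations(self, by = "level")
  expect_true(all(is.na(cc$r) | abs(cc$r - 1) < 1e-12))
})
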