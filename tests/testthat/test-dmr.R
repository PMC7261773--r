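test_that("window tiling enumerates 25-bp offsets with a truncated tail", {
  w <- tile_windows(c(chr1 = 150))
  expect_equal(w$start, seq(0L, 125L, 25L))
  expect_equal(w[start == 125, end], 150L)
  w2 <- tile_windows(c(chr1 = 100))
  expect_equal(w2$start, c(0L, 25L, 50L, 75L))
  expect_true(all(w2$end == 100L))
  w3 <- tile_windows(c(chr1 = 10))
  expect_equal(w3, data.table(chrom = "chr1", start = 0L, end = 10L))
  expect_error(tile_windows(c(chr1 = -5)), "positive")
  expect_error(tile_windows(c(chr1 = 100), size = 10, step = 20), "step")
})

test_that("windows gather their sites and respect the min_sites filter", {
  # sites at 10,40,60,90 fall in windows starting 0 (all) and 25 (40,60,90)
  pair <- make_pair(rep(0.2, 4), rep(0.8, 4), pos = c(10L, 40L, 60L, 90L))
  win <- tile_windows(c(chr1 = 115))
  tw <- test_windows(pair, win, "CHH", min_sites = 4)
  expect_equal(tw$start, 0L)
  expect_equal(tw$n_sites, 4L)
  tw2 <- test_windows(pair, win, "CHH", min_sites = 3)
  expect_equal(tw2$start, c(0L, 25L))
  expect_equal(tw2$n_sites, c(4L, 3L))
  # BH family = tested windows only
  expect_equal(tw2$q, bh_adjust(tw2$p))
})

test_that("identical levels across a window can never become a DMR", {
  pair <- make_pair(rep(0.4, 8), rep(0.4, 8), pos = seq(0L, 70L, 10L))
  tw <- test_windows(pair, tile_windows(c(chr1 = 100)), "CHH")
  expect_true(all(tw$p == 1))
  expect_equal(nrow(call_dmrs(tw)), 0L)
})

test_that("raw null p-values are roughly uniform for iid windows", {
  # iid binomial levels, no spatial structure: the chi-square approximation
  # should hold to within binomial bounds at 200+ windows
  set.seed(23)
  n_sites <- 2000
  pos <- seq(2L, by = 4L, length.out = n_sites)
  la <- rbinom(n_sites, 12, 0.3) / 12
  lb <- rbinom(n_sites, 12, 0.3) / 12
  pair <- make_pair(la, lb, pos = pos)
  L <- max(pos) + 10
  tw <- test_windows(pair, tile_windows(c(chr1 = L)), "CHH")
  frac <- mean(tw$p < 0.05)
  bound <- qnorm(0.995) * sqrt(0.05 * 0.95 / nrow(tw))
  expect_gt(nrow(tw), 200)
  expect_lt(abs(frac - 0.05), bound + 1e-9)
})

test_that("significant windows become DMRs with trend from the fold change", {
  tw <- data.table(chrom = "chr1", start = c(0L, 25L, 50L),
                   end = c(100L, 125L, 150L), context = "CHH",
                   n_sites = 5L,
                   mean_a = c(0.2, 0.4, 0.3), mean_b = c(0.5, 0.4, 0.3),
                   h = 5, p = c(0.001, 0.2, 0.004),
                   q = c(0.04, 0.6, 0.06))
  d <- call_dmrs(tw)
  expect_equal(nrow(d), 1L)
  expect_equal(d$fold_change, 2.5)
  expect_equal(d$trend, "hyper")
  # q = 0.06 window is not significant; fc = 1 window is filtered out
  tw2 <- copy(tw)[3, q := 0.01][3, mean_b := 0.3][3, mean_a := 0.3]
  d2 <- call_dmrs(tw2)
  expect_false(50 %in% d2$start)
  d3 <- call_dmrs(tw2, fc_threshold = NULL)
  expect_true(50 %in% d3$start)
  expect_error(call_dmrs(tw[, !"q"]), "q-values")
})

test_that("same-trend neighbours merge, opposite trends never do", {
  pair <- make_pair(rep(0.2, 10), rep(0.8, 10), pos = seq(100L, 230L, 14L))
  hh <- make_dmrs("chr1", c(100, 125), c(200, 225), trend = "hyper",
                  q = c(0.01, 0.002))
  m <- merge_adjacent(hh, pair)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 225L)
  expect_equal(m$q_value, 0.002)
  expect_equal(m$n_windows, 2L)

  hx <- make_dmrs("chr1", c(100, 125), c(200, 225),
                  trend = c("hyper", "hypo"))
  m2 <- merge_adjacent(hx, pair)
  expect_equal(nrow(m2), 2L)
  expect_equal(sort(m2$trend), c("hyper", "hypo"))
})

test_that("a chain of k overlapping windows collapses to one region", {
  k <- 6
  starts <- 100 + 25 * (0:(k - 1))
  pair <- make_pair(rep(0.2, 21), rep(0.8, 21),
                    pos = seq(100L, 340L, 12L))
  d <- make_dmrs("chr1", starts, starts + 100, trend = "hypo")
  m <- merge_adjacent(d, pair)
  expect_equal(nrow(m), 1L)
  expect_equal(m$end - m$start, 100L + 25L * (k - 1L))
})

test_that("merging is idempotent and equals the IRanges reduce oracle", {
  set.seed(29)
  starts <- sort(sample(seq(0L, 5000L, 25L), 60))
  d <- make_dmrs("chr1", starts, starts + 100,
                 trend = sample(c("hyper", "hypo"), 60, replace = TRUE),
                 q = runif(60, 1e-5, 0.04))
  d$trend <- sample(c("hyper", "hypo"), 60, replace = TRUE)
  pair <- make_pair(runif(300, 0.1, 0.9), runif(300, 0.1, 0.9),
                    pos = seq(0L, 5990L, 20L))
  m1 <- merge_adjacent(d, pair)
  m2 <- merge_adjacent(m1, pair)
  expect_equal(as.data.table(m2)[, .(chrom, start, end, context, trend)],
               as.data.table(m1)[, .(chrom, start, end, context, trend)])
  expect_gte(sum(m1$end - m1$start), 0)
  # oracle: interval union per trend via IRanges::reduce
  for (tr in c("hyper", "hypo")) {
    sub <- as.data.table(d)[trend == tr]
    red <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
    got <- as.data.table(m1)[trend == tr]
    expect_equal(got$start, IRanges::start(red) - 1L)
    expect_equal(got$end, IRanges::end(red))
  }
  # covered bases never decrease under merging
  union_width <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(d$start + 1L, d$end))))
  expect_gte(sum(m1$end - m1$start), union_width)
  expect_error(merge_adjacent(d[order(-start)], pair), "sorted")
})

test_that("gene-region annotation is strand-aware", {
  genes <- data.table(gene_id = c("gp", "gm"), chrom = "chr1",
                      start = c(5000L, 20000L), end = c(8000L, 23000L),
                      strand = c("+", "-"))
  d <- make_dmrs("chr1",
                 c(4500, 8100, 23100, 4950),
                 c(4600, 8200, 23200, 5050))
  ann <- annotate_dmrs(d, genes)$annotations
  reg <- function(s) ann[start == s, sort(paste(gene_id, region))]
  expect_equal(reg(4500), "gp upstream")
  expect_equal(reg(8100), "gp downstream")
  expect_equal(reg(23100), "gm upstream")   # strand flip
  expect_equal(reg(4950), c("gp gene_body", "gp upstream"))
  expect_error(annotate_dmrs(d, genes, flank = -1), "flank")
})

test_that("annotation summary reports the genic DMR percentage", {
  genes <- data.table(gene_id = "g1", chrom = "chr1",
                      start = 5000L, end = 8000L, strand = "+")
  d <- make_dmrs("chr1", c(6000, 50000), c(6100, 50100))
  ann <- annotate_dmrs(d, genes)
  expect_equal(ann$summary$pct_genic, 50)
  expect_equal(ann$summary$n_dmrs, 2L)
})

test_that("length histogram tallies DMR lengths against breaks", {
  d <- make_dmrs("chr1", c(0, 200, 500), c(100, 325, 750))
  h <- length_distribution(d, breaks = 200)
  expect_equal(h$count, c(2L, 1L))
  expect_equal(h$pct[1], 100 * 2 / 3)
  d2 <- make_dmrs("chr1", c(0, 200), c(100, 300))
  h2 <- length_distribution(d2, breaks = c(100, 200))
  expect_equal(h2[from == 100, count], 2L)
  expect_error(length_distribution(d, breaks = c(5, 5)), "increasing")
})

test_that("calling a sample against itself yields no DMRs", {
  sim <- small_sim()
  self <- pair_samples(sim$sample_a, sim$sample_a)
  tw <- test_windows(self, tile_windows(sim$config$chrom_lengths), "CHH")
  expect_true(all(tw$p == 1))
  expect_equal(nrow(call_dmrs(tw)), 0L)
})

test_that("swapping samples mirrors DMRs with reciprocal fold changes", {
  sim <- small_sim()
  win <- tile_windows(sim$config$chrom_lengths)
  fwd <- call_dmrs(test_windows(sim$pair, win, "CHH"))
  rev <- call_dmrs(test_windows(swap_pair(sim$pair), win, "CHH"))
  expect_gt(nrow(fwd), 0L)
  setorder(fwd, chrom, start)
  setorder(rev, chrom, start)
  expect_equal(rev[, .(chrom, start, end, q_value)],
               fwd[, .(chrom, start, end, q_value)])
  expect_equal(rev$trend,
               ifelse(fwd$trend == "hyper", "hypo", "hyper"))
  expect_equal(rev$fold_change, 1 / fwd$fold_change)
})
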