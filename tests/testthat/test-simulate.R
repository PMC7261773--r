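test_that("trinucleotide contexts are assigned on both strands", {
  # CCGG: plus strand C0 is CHG (C-C-G), C1 is CG; the mirrored minus-strand
  # cytosines are the CG partner at position 2 and a CHG at position 3
  cat <- windmr:::context_catalog_chrom(c("C", "C", "G", "G"), "chr1")
  setorder(cat, pos, strand)
  expect_equal(cat$pos, 0:3)
  expect_equal(cat$strand, c("+", "+", "-", "-"))
  expect_equal(cat$context, c("CHG", "CG", "CG", "CHG"))
})

test_that("a GC-free genome has an empty catalog", {
  cfg <- simulation_config(seed = 1, chrom_lengths = c(chr1 = 1000),
                           gc_fraction = 0)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$catalog), 0L)
  expect_false(grepl("[CG]", g$sequences[["chr1"]]))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- simulation_config(seed = 9, chrom_lengths = c(chr1 = 3e4),
                           n_dmrs = c(CG = 0, CHG = 0, CHH = 3),
                           n_genes = 3)
  d1 <- file.path(tempdir(), "sim1")
  d2 <- file.path(tempdir(), "sim2")
  s1 <- simulate_methylome_experiment(cfg, outdir = d1)
  s2 <- simulate_methylome_experiment(cfg, outdir = d2)
  for (f in c("report_a", "report_b", "gff", "expression", "truth_dmrs")) {
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]))
  }
})

test_that("simulated reports parse cleanly and match the catalog", {
  sim <- small_sim()
  path <- tempfile()
  write_cytosine_report(sim$sample_a, path)
  parsed <- read_cytosine_report(path)
  expect_equal(nrow(parsed), nrow(sim$genome$catalog))
  expect_equal(parsed$context, sim$genome$catalog$context)
})

test_that("empirical context means track the configured levels", {
  sim <- small_sim()
  pair <- sim$pair
  means <- pair[, .(m = mean(level_a)), by = context]
  cfg_means <- sim$config$context_means
  for (ctx in names(cfg_means))
    expect_lt(abs(means[context == ctx, m] - cfg_means[[ctx]]), 0.02)
})

test_that("planted DMRs shift sample B in the planted direction", {
  sim <- small_sim()
  pair <- sim$pair
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i]
    sub <- pair[chrom == tr$chrom & pos >= tr$start & pos < tr$end &
                  context == tr$context]
    # joint coverage can drop the odd catalog site below the planting count
    expect_gte(nrow(sub), sim$config$dmr_min_sites - 2L)
    dlt <- mean(sub$level_b) - mean(sub$level_a)
    # hypo shifts clip at zero on lowly methylated segments, so only a
    # weak bound holds there; hyper shifts are always substantial
    if (tr$trend == "hyper") expect_gt(dlt, 0.05) else expect_lt(dlt, 0.05)
  }
})

test_that("planted gene-body DMRs sit inside their genes", {
  sim <- small_sim()
  body <- sim$truth[placement == "gene_body"]
  expect_gt(nrow(body), 0L)
  g <- as.data.table(sim$genes)
  for (i in seq_len(nrow(body))) {
    gi <- g[gene_id == body$gene_id[i]]
    expect_true(body$start[i] >= gi$start && body$end[i] <= gi$end)
  }
})

test_that("coupled genes carry the configured expression increment", {
  sim <- small_sim()
  gt <- sim$gene_truth
  cfg <- sim$config
  coupled_up <- gt[coupled == TRUE & body_dmr == "hypo"]
  if (nrow(coupled_up)) {
    expect_true(all(coupled_up$class_true == "increased"))
    expect_true(all(coupled_up$lfc_true >=
                      cfg$deg_lfc_base + cfg$couple_lfc))
  }
  coupled_dn <- gt[coupled == TRUE & body_dmr == "hyper"]
  if (nrow(coupled_dn)) {
    expect_true(all(coupled_dn$class_true == "decreased"))
    expect_true(all(coupled_dn$lfc_true <=
                      -(cfg$deg_lfc_base + cfg$couple_lfc)))
  }
  # truth classes partition the gene set
  expect_equal(nrow(gt), cfg$n_genes)
  expect_true(all(gt$class_true %in%
                    c("increased", "decreased", "non_diff",
                      "non_expressed")))
})

test_that("recovery evaluation applies the overlap and trend rules", {
  truth <- data.table(chrom = "chr1", start = c(100L, 1000L),
                      end = c(300L, 1200L), context = "CHH",
                      trend = c("hyper", "hypo"), delta = 0.3,
                      placement = "intergenic", gene_id = NA_character_)
  exact <- make_dmrs("chr1", c(100, 1000), c(300, 1200),
                     trend = c("hyper", "hypo"))
  r <- evaluate_recovery(exact, truth)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$precision, 1)

  none <- exact[0]
  r0 <- evaluate_recovery(none, truth)
  expect_equal(r0$sensitivity, 0)
  expect_true(is.na(r0$precision))

  # 40% overlap fails the 50% rule; wrong trend never matches
  shifted <- make_dmrs("chr1", 220, 420, trend = "hyper")
  r1 <- evaluate_recovery(shifted, truth)
  expect_equal(r1$sensitivity, 0)
  wrong <- make_dmrs("chr1", 100, 300, trend = "hypo")
  expect_equal(evaluate_recovery(wrong, truth)$sensitivity, 0)
})

test_that("seed is mandatory and config values are validated", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, gc_fraction = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(seed = 1, dmr_delta = 2), "dmr_delta")
  expect_error(simulation_config(seed = 1, chrom_lengths = c(100, 200)),
               "named")
})
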