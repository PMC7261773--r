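library(data.table)

# simulations are expensive; build each scenario once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# small end-to-end scenario (200 kb) for unit tests
small_sim <- function() fixture("small_sim", function() {
  cfg <- simulation_config(seed = 5, chrom_lengths = c(chr1 = 2e5),
                           n_dmrs = c(CG = 0, CHG = 0, CHH = 30),
                           n_genes = 25)
  sim <- simulate_methylome_experiment(cfg)
  sim$config <- cfg
  sim$pair <- pair_samples(sim$sample_a, sim$sample_b)
  sim
})

# the default planted scenario (2 x 1 Mb, 200 CHH DMRs), fixed seed
default_sim <- function() fixture("default_sim", function() {
  cfg <- simulation_config(seed = 42)
  sim <- simulate_methylome_experiment(cfg)
  sim$config <- cfg
  sim$pair <- pair_samples(sim$sample_a, sim$sample_b)
  sim
})

# 1-Mb null scenario: no planted DMRs
null_sim <- function() fixture("null_sim", function() {
  cfg <- simulation_config(seed = 7, chrom_lengths = c(chr1 = 1e6),
                           n_dmrs = c(CG = 0, CHG = 0, CHH = 0))
  genome <- generate_genome(cfg)
  meth <- simulate_methylome_pair(cfg, genome$catalog)
  list(config = cfg,
       pair = pair_samples(meth$sample_a, meth$sample_b))
})

# construct a methylome_pair directly from levels (denominator 20 counts,
# so tenths and twentieths are represented exactly)
make_pair <- function(level_a, level_b, context = "CHH",
                      chrom = "chr1", pos = NULL) {
  n <- length(level_a)
  if (is.null(pos)) pos <- seq(0L, by = 10L, length.out = n)
  dt <- data.table(chrom = chrom, pos = as.integer(pos), strand = "+",
                   context = context,
                   n_meth_a = as.integer(round(level_a * 20)),
                   n_unmeth_a = as.integer(20 - round(level_a * 20)),
                   n_meth_b = as.integer(round(level_b * 20)),
                   n_unmeth_b = as.integer(20 - round(level_b * 20)))
  dt[, `:=`(cov_a = n_meth_a + n_unmeth_a, cov_b = n_meth_b + n_unmeth_b)]
  dt[, `:=`(level_a = n_meth_a / cov_a, level_b = n_meth_b / cov_b)]
  setorder(dt, chrom, pos, strand)
  setattr(dt, "min_total_reads", 3)
  setattr(dt, "class", c("methylome_pair", class(dt)))
  dt[]
}

# swap the two samples of a pair
swap_pair <- function(pair) {
  sw <- copy(as.data.table(pair))
  setnames(sw,
           c("n_meth_a", "n_unmeth_a", "cov_a", "level_a",
             "n_meth_b", "n_unmeth_b", "cov_b", "level_b"),
           c("n_meth_b", "n_unmeth_b", "cov_b", "level_b",
             "n_meth_a", "n_unmeth_a", "cov_a", "level_a"))
  setattr(sw, "min_total_reads", attr(pair, "min_total_reads"))
  setattr(sw, "class", class(pair))
  sw
}

# minimal dmr_set constructor for annotation / merge unit tests
make_dmrs <- function(chrom, start, end, context = "CHH", trend = "hyper",
                      q = 0.01, fc = NULL) {
  n <- length(start)
  dt <- data.table(chrom = rep_len(chrom, n), start = as.integer(start),
                   end = as.integer(end),
                   context = rep_len(context, n),
                   n_sites = 5L, mean_a = 0.2, mean_b = 0.5,
                   fold_change = rep_len(fc %||% 2.5, n),
                   trend = rep_len(trend, n),
                   q_value = rep_len(q, n), n_windows = 1L)
  setorder(dt, chrom, start, end)
  setattr(dt, "alpha", 0.05)
  setattr(dt, "merged", FALSE)
  setattr(dt, "class", c("dmr_set", class(dt)))
  dt[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
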