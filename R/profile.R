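#' Per-site methylation level
#'
#' The level of a cytosine is the fraction of reads supporting methylation,
#' `n_meth / (n_meth + n_unmeth)`. Vectorised.
#'
#' @param n_meth,n_unmeth Non-negative read counts.
#' @return Numeric vector of levels in `[0, 1]`.
#' @export
site_level <- function(n_meth, n_unmeth) {
  total <- n_meth + n_unmeth
  if (any(total <= 0))
    stop_windmr("site_level is undefined at zero total coverage")
  n_meth / total
}

#' Pair two cytosine samples under a joint coverage filter
#'
#' Keeps the intersection of sites (by chromosome, position, strand and
#' context) covered by at least `min_total_reads` reads in *both* samples,
#' and computes per-site methylation levels for each.
#'
#' @param sample_a,sample_b Site tables from [read_cytosine_report()] (or the
#'   simulator), sorted by `(chrom, pos, strand)`.
#' @param min_total_reads Joint coverage threshold (default 3 reads).
#' @return A `methylome_pair`: a `data.table` with site keys, per-sample
#'   counts/coverage and `level_a`, `level_b`.
#' @export
pair_samples <- function(sample_a, sample_b, min_total_reads = 3) {
  a <- as.data.table(sample_a)
  b <- as.data.table(sample_b)
  for (s in list(a, b)) {
    o <- order(s$chrom, s$pos, s$strand, method = "radix")
    if (!identical(o, seq_len(nrow(s))))
      stop_windmr("input samples must be sorted by (chrom, pos, strand)")
  }
  keys <- c("chrom", "pos", "strand", "context")
  a <- a[(n_meth + n_unmeth) >= min_total_reads,
         .(chrom, pos, strand, context, n_meth_a = n_meth,
           n_unmeth_a = n_unmeth)]
  b <- b[(n_meth + n_unmeth) >= min_total_reads,
         .(chrom, pos, strand, context, n_meth_b = n_meth,
           n_unmeth_b = n_unmeth)]
  pair <- merge(a, b, by = keys, sort = TRUE)
  pair[, `:=`(cov_a = n_meth_a + n_unmeth_a, cov_b = n_meth_b + n_unmeth_b)]
  pair[, `:=`(level_a = n_meth_a / cov_a, level_b = n_meth_b / cov_b)]
  setorder(pair, chrom, pos, strand)
  setattr(pair, "min_total_reads", min_total_reads)
  setattr(pair, "class", c("methylome_pair", class(pair)))
  pair[]
}

#' @export
print.methylome_pair <- function(x, ...) {
  cat("Jointly covered methylome pair:", nrow(x), "sites",
      sprintf("(min coverage %s in both samples)\n",
              attr(x, "min_total_reads")))
  if (nrow(x)) {
    s <- as.data.table(x)[, .(n_sites = .N,
                              mean_level_a = mean(level_a),
                              mean_level_b = mean(level_b)), by = context]
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Call methylated cytosines and per-context methylation rates
#'
#' A covered site (total reads `>= min_total_reads`) is called methylated
#' (an mC) when it has at least `min_meth_reads` methylated reads. The
#' per-context methylation rate is the mC count over the covered-site count.
#'
#' @param sample A site table.
#' @param min_total_reads Coverage threshold for a site to be assessable.
#' @param min_meth_reads Methylated-read threshold for an mC call.
#' @return A list of class `mc_calls` with elements `sites` (the covered
#'   sites with an `is_mc` flag) and `summary` (per-context and total
#'   `n_covered`, `n_mc`, `rate`).
#' @export
call_mcs <- function(sample, min_total_reads = 3, min_meth_reads = 1) {
  if (min_total_reads < 0 || min_meth_reads < 0)
    stop_windmr("thresholds must be >= 0")
  dt <- as.data.table(sample)
  dt <- dt[(n_meth + n_unmeth) >= min_total_reads]
  dt[, is_mc := n_meth >= min_meth_reads]
  per <- dt[, .(n_covered = .N, n_mc = sum(is_mc)), keyby = context]
  per <- per[CONTEXTS, on = "context"]
  per[is.na(n_covered), `:=`(n_covered = 0L, n_mc = 0L)]
  tot <- data.table(context = "all", n_covered = nrow(dt),
                    n_mc = sum(dt$is_mc))
  summary <- rbind(per, tot)
  summary[, rate := fifelse(n_covered > 0, n_mc / n_covered, NA_real_)]
  out <- list(sites = dt[], summary = summary[])
  class(out) <- "mc_calls"
  out
}

#' @export
print.mc_calls <- function(x, ...) {
  cat("Methylcytosine calls\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Tiled bin profiles of methylation density and level
#'
#' Tiles each chromosome into non-overlapping bins (default 50 kb, last bin
#' truncated) and reports, per context and in total: the number of report
#' sites, covered sites and mCs, the mC density and cytosine-site density
#' (counts over the bin's actual length), and the mean per-site level over
#' covered sites (`NA` for bins with none).
#'
#' @param sample A site table.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 50000).
#' @param min_total_reads,min_meth_reads mC-call thresholds (see
#'   [call_mcs()]).
#' @return A `data.table`, one row per bin x context (including `"all"`).
#' @export
bin_profiles <- function(sample, chrom_lengths, bin_size = 50000,
                         min_total_reads = 3, min_meth_reads = 1) {
  chrom_lengths <- check_chrom_lengths(chrom_lengths)
  if (bin_size <= 0) stop_windmr("bin_size must be positive")
  dt <- as.data.table(sample)
  if (nrow(dt)) {
    if (!all(dt$chrom %in% names(chrom_lengths)))
      stop_windmr("sites on chromosomes absent from chrom_lengths")
    over <- dt[pos >= chrom_lengths[chrom]]
    if (nrow(over))
      stop_windmr("site at ", over$chrom[1], ":", over$pos[1] + 1L,
                  " beyond declared chromosome length")
  }
  bins <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    s <- seq(0L, by = as.integer(bin_size),
             length.out = ceiling(L / bin_size))
    data.table(chrom = ch, bin_start = as.integer(s),
               bin_end = as.integer(pmin(s + bin_size, L)))
  }))
  grid <- bins[, .(context = c(CONTEXTS, "all")), by = .(chrom, bin_start, bin_end)]
  dt[, `:=`(total = n_meth + n_unmeth,
            bin_start = as.integer((pos %/% bin_size) * bin_size))]
  dt[, covered := total >= min_total_reads]
  dt[, is_mc := covered & n_meth >= min_meth_reads]
  dt[, level := fifelse(total > 0, n_meth / total, NA_real_)]
  agg <- function(d)
    d[, .(n_sites = .N, n_covered = sum(covered), n_mc = sum(is_mc),
          mean_level = if (any(covered)) mean(level[covered]) else NA_real_),
      by = .(chrom, bin_start, context)]
  per <- agg(dt)
  tot <- agg(copy(dt)[, context := "all"])
  stats <- rbind(per, tot)
  out <- merge(grid, stats, by = c("chrom", "bin_start", "context"),
               all.x = TRUE)
  for (col in c("n_sites", "n_covered", "n_mc"))
    out[is.na(get(col)), (col) := 0L]
  out[, `:=`(mc_density = n_mc / (bin_end - bin_start),
             c_density = n_sites / (bin_end - bin_start))]
  setcolorder(out, c("chrom", "bin_start", "bin_end", "context", "n_sites",
                     "n_covered", "n_mc", "c_density", "mc_density",
                     "mean_level"))
  setorder(out, chrom, bin_start, context)
  out[]
}

#' Per-chromosome cross-sample correlations
#'
#' Correlates the two samples of a [pair_samples()] table per chromosome and
#' context (plus `"all"`), either on per-site methylation levels
#' (`by = "level"`, product-moment correlation) or on binary mC-call
#' indicators (`by = "presence"`, position concordance; a phi coefficient).
#' Combinations with fewer than `min_sites` shared sites or zero variance in
#' either vector are reported as `NA`.
#'
#' @param pair A `methylome_pair`.
#' @param by `"level"` or `"presence"`.
#' @param min_meth_reads mC-call threshold for `by = "presence"`.
#' @param min_sites Minimum shared sites for a defined coefficient.
#' @return A `data.table` with `chrom`, `context`, `n_sites`, `r`.
#' @export
chromosome_correlations <- function(pair, by = c("level", "presence"),
                                    min_meth_reads = 1, min_sites = 3) {
  by <- match.arg(by)
  dt <- as.data.table(pair)
  if (by == "presence") {
    dt <- copy(dt)[, `:=`(level_a = as.numeric(n_meth_a >= min_meth_reads),
                          level_b = as.numeric(n_meth_b >= min_meth_reads))]
  }
  corr <- function(d) {
    if (nrow(d) < min_sites) return(NA_real_)
    if (stats::var(d$level_a) == 0 || stats::var(d$level_b) == 0)
      return(NA_real_)
    cor(d$level_a, d$level_b)
  }
  one <- function(d)
    d[, .(n_sites = .N, r = corr(.SD)), by = .(chrom, context)]
  out <- rbind(one(dt), one(copy(dt)[, context := "all"]))
  setorder(out, chrom, context)
  out[]
}

#' Per-site methylation divergence between the two samples
#'
#' Restricted to sites that are mC calls in at least one sample, classifies
#' each site by the fold change of sample B over sample A: increased when
#' `level_b / level_a > fc_threshold`, decreased when
#' `level_a / level_b > fc_threshold`; sites where one level is zero and the
#' other positive fall in the `>= strong_fc` class of the nonzero direction.
#' Percentages are reported per context and in total.
#'
#' @param pair A `methylome_pair`.
#' @param fc_threshold Per-site fold-change threshold for differential
#'   methylation (default 1.2).
#' @param strong_fc Threshold of the strong-change subclass (default 2).
#' @param min_meth_reads mC-call threshold defining eligibility.
#' @return A `divergence_summary` `data.table`: per context and total,
#'   `n_eligible`, `pct_increased`, `pct_decreased`,
#'   `pct_increased_ge2fold`, `pct_decreased_ge2fold`, `pct_total_variant`.
#' @export
divergence_summary <- function(pair, fc_threshold = 1.2, strong_fc = 2.0,
                               min_meth_reads = 1) {
  dt <- as.data.table(pair)
  dt <- dt[n_meth_a >= min_meth_reads | n_meth_b >= min_meth_reads]
  if (!nrow(dt))
    stop_windmr("no sites are mC calls in either sample")
  dt <- copy(dt)
  dt[, `:=`(
    increased = (level_a == 0 & level_b > 0) |
      (level_a > 0 & level_b / level_a > fc_threshold),
    decreased = (level_b == 0 & level_a > 0) |
      (level_b > 0 & level_a / level_b > fc_threshold))]
  dt[, `:=`(
    inc2 = (level_a == 0 & level_b > 0) |
      (level_a > 0 & level_b / level_a > strong_fc),
    dec2 = (level_b == 0 & level_a > 0) |
      (level_b > 0 & level_a / level_b > strong_fc))]
  one <- function(d)
    d[, .(n_eligible = .N,
          pct_increased = 100 * mean(increased),
          pct_decreased = 100 * mean(decreased),
          pct_increased_ge2fold = 100 * mean(inc2),
          pct_decreased_ge2fold = 100 * mean(dec2)),
      by = context]
  out <- rbind(one(dt), one(copy(dt)[, context := "all"]))
  out[, pct_total_variant := pct_increased + pct_decreased]
  setattr(out, "fc_threshold", fc_threshold)
  setattr(out, "class", c("divergence_summary", class(out)))
  out[]
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf(
    "Per-site methylation divergence (fold-change threshold %s)\n",
    attr(x, "fc_threshold")))
  print(as.data.table(x), row.names = FALSE, digits = 4)
  invisible(x)
}
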