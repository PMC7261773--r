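#' Call DMRs from tested windows
#'
#' Windows with BH-adjusted `q < alpha` become differentially methylated
#' regions. The fold change of a window is `mean(level_b) / mean(level_a)`
#' over its sites; the trend is `hyper` when the fold change exceeds 1
#' (sample B more methylated) and `hypo` otherwise. Windows whose sample-A
#' mean is zero get an infinite fold change and trend `hyper`. When
#' `fc_threshold` is set (default 1.2), a significant window must
#' additionally satisfy `|log(fold change)| > log(fc_threshold)`.
#'
#' @param tested_windows Output of [test_windows()].
#' @param alpha Significance level on q-values (default 0.05).
#' @param fc_threshold Region fold-change filter; `NULL` disables it.
#' @return A `dmr_set` `data.table`: `chrom`, `start`, `end`, `context`,
#'   `n_sites`, `mean_a`, `mean_b`, `fold_change`, `trend`, `q_value`,
#'   `n_windows`.
#' @export
call_dmrs <- function(tested_windows, alpha = 0.05, fc_threshold = 1.2) {
  tw <- as.data.table(tested_windows)
  if (nrow(tw) && (!"q" %in% names(tw) || anyNA(tw$q)))
    stop_windmr("windows must carry q-values (run test_windows first)")
  d <- tw[q < alpha]
  d <- d[!(mean_a == 0 & mean_b == 0)]
  if (nrow(d)) {
    d[, fold_change := mean_b / mean_a]
    d[, trend := fifelse(fold_change > 1, "hyper", "hypo")]
    if (!is.null(fc_threshold) && !is.na(fc_threshold))
      d <- d[abs(log(fold_change)) > log(fc_threshold)]
  } else {
    d[, `:=`(fold_change = numeric(), trend = character())]
  }
  out <- d[, .(chrom, start, end, context, n_sites, mean_a, mean_b,
               fold_change, trend, q_value = q, n_windows = 1L)]
  setorder(out, chrom, start, end)
  setattr(out, "alpha", alpha)
  setattr(out, "fc_threshold", fc_threshold)
  setattr(out, "merged", FALSE)
  setattr(out, "class", c("dmr_set", class(out)))
  out[]
}

#' @export
print.dmr_set <- function(x, ...) {
  merged <- isTRUE(attr(x, "merged"))
  cat(nrow(x), if (merged) "merged" else "window-level",
      sprintf("DMRs (q < %s)\n", attr(x, "alpha")))
  if (nrow(x)) {
    s <- as.data.table(x)[, .(n = .N,
                              median_length = as.numeric(median(end - start))),
                          by = .(context, trend)]
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Merge adjacent same-trend DMRs
#'
#' DMRs of the same context and trend that overlap or abut (next start
#' `<= current end + max_gap`) collapse into a single region spanning their
#' union. The merged fold change is recomputed from all jointly covered
#' sites of the context inside the merged interval; the q-value is the
#' minimum over members and `n_windows` their count. Opposite-trend
#' neighbours are never merged.
#'
#' @param dmrs A `dmr_set` sorted by `(chrom, start)`.
#' @param pair The `methylome_pair` the DMRs were called from (used to
#'   recompute merged fold changes).
#' @param max_gap Maximum gap in bp between mergeable regions (default 0 =
#'   overlapping or abutting).
#' @return A merged `dmr_set`.
#' @export
merge_adjacent <- function(dmrs, pair, max_gap = 0) {
  d <- as.data.table(dmrs)
  if (max_gap < 0) stop_windmr("max_gap must be >= 0")
  if (!nrow(d)) {
    out <- d[, .(chrom, start, end, context, n_sites, mean_a, mean_b,
                 fold_change, trend, q_value, n_windows)]
    setattr(out, "alpha", attr(dmrs, "alpha"))
    setattr(out, "merged", TRUE)
    setattr(out, "class", c("dmr_set", class(out)))
    return(out[])
  }
  o <- order(d$chrom, d$start, method = "radix")
  if (!identical(o, seq_len(nrow(d))))
    stop_windmr("DMRs must be sorted by (chrom, start)")
  d <- copy(d)
  setorder(d, chrom, context, trend, start, end)
  # new run whenever a region starts beyond the running max end (+ gap);
  # the first row's fill keeps it in run 0 since start < end always
  d[, run := cumsum(start > shift(cummax(end), fill = end[1]) + max_gap),
    by = .(chrom, context, trend)]
  merged <- d[, .(start = min(start), end = max(end),
                  q_value = min(q_value), n_windows = sum(n_windows)),
              by = .(chrom, context, trend, run)]
  merged[, run := NULL]
  sites <- as.data.table(pair)[, .(chrom, pos, context, level_a, level_b)]
  out <- copy(merged)
  rs <- lapply(seq_len(nrow(out)), function(i) {
    s <- sites[chrom == out$chrom[i] & context == out$context[i] &
                 pos >= out$start[i] & pos < out$end[i]]
    c(nrow(s), mean(s$level_a), mean(s$level_b))
  })
  rs <- do.call(rbind, rs)
  out[, `:=`(n_sites = as.integer(rs[, 1]), mean_a = rs[, 2],
             mean_b = rs[, 3])]
  out[, fold_change := fifelse(mean_a == 0, Inf, mean_b / mean_a)]
  setcolorder(out, c("chrom", "start", "end", "context", "n_sites",
                     "mean_a", "mean_b", "fold_change", "trend", "q_value",
                     "n_windows"))
  setorder(out, chrom, start, end)
  setattr(out, "alpha", attr(dmrs, "alpha"))
  setattr(out, "fc_threshold", attr(dmrs, "fc_threshold"))
  setattr(out, "merged", TRUE)
  setattr(out, "class", c("dmr_set", class(out)))
  out[]
}

# strand-aware gene region table: body, upstream and downstream flanks
gene_regions <- function(genes, flank = 2000) {
  g <- as.data.table(genes)
  if (flank < 0) stop_windmr("flank must be >= 0")
  fl <- as.integer(flank)
  plus <- g$strand == "+"
  body <- g[, .(gene_id, chrom, start, end, region = "gene_body")]
  up <- data.table(gene_id = g$gene_id, chrom = g$chrom,
                   start = ifelse(plus, pmax(0L, g$start - fl), g$end),
                   end = ifelse(plus, g$start, g$end + fl),
                   region = "upstream")
  down <- data.table(gene_id = g$gene_id, chrom = g$chrom,
                     start = ifelse(plus, g$end, pmax(0L, g$start - fl)),
                     end = ifelse(plus, g$end + fl, g$start),
                     region = "downstream")
  out <- rbind(body, up, down)
  out[, `:=`(start = as.integer(start), end = as.integer(end))]
  out[end > start]
}

#' Annotate DMRs against gene regions
#'
#' Each gene contributes a body `[start, end)` and strand-aware 2-kb
#' upstream and downstream flanks. A DMR annotates every (gene, region) pair
#' it overlaps by at least 1 bp; multiple assignments are allowed. DMRs
#' overlapping no region are intergenic.
#'
#' @param dmrs A `dmr_set`.
#' @param genes Gene models from [read_gene_models()].
#' @param flank Flank width in bp (default 2000).
#' @return A list of class `dmr_annotation`: `annotations` (one row per
#'   DMR-gene-region overlap, with `overlap_bp` and the DMR's trend) and
#'   `summary` (percentage of DMRs in any gene region, and per-region DMR
#'   counts).
#' @export
annotate_dmrs <- function(dmrs, genes, flank = 2000) {
  d <- as.data.table(dmrs)
  regions <- gene_regions(genes, flank)
  d <- copy(d)[, dmr_id := .I]
  if (nrow(d) && nrow(regions)) {
    dgr <- GenomicRanges::GRanges(d$chrom,
                                  IRanges::IRanges(d$start + 1L, d$end))
    rgr <- GenomicRanges::GRanges(regions$chrom,
                                  IRanges::IRanges(regions$start + 1L,
                                                   regions$end))
    hits <- GenomicRanges::findOverlaps(dgr, rgr, minoverlap = 1L)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(d$end[qh], regions$end[sh]) -
      pmax(d$start[qh], regions$start[sh])
    ann <- data.table(dmr_id = d$dmr_id[qh],
                      chrom = d$chrom[qh], start = d$start[qh],
                      end = d$end[qh], context = d$context[qh],
                      trend = d$trend[qh],
                      gene_id = regions$gene_id[sh],
                      region = regions$region[sh],
                      overlap_bp = as.integer(ov))
    setorder(ann, chrom, start, gene_id, region)
  } else {
    ann <- data.table(dmr_id = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      context = character(), trend = character(),
                      gene_id = character(), region = character(),
                      overlap_bp = integer())
  }
  genic <- unique(ann$dmr_id)
  region_counts <- ann[, .(n_dmrs = uniqueN(dmr_id)), by = region]
  summary <- list(
    n_dmrs = nrow(d),
    n_genic = length(genic),
    pct_genic = if (nrow(d)) 100 * length(genic) / nrow(d) else NA_real_,
    region_counts = region_counts[])
  out <- list(annotations = ann[], summary = summary)
  class(out) <- "dmr_annotation"
  out
}

#' @export
print.dmr_annotation <- function(x, ...) {
  cat(sprintf("%d of %d DMRs (%.1f%%) overlap a gene region\n",
              x$summary$n_genic, x$summary$n_dmrs,
              x$summary$pct_genic))
  print(x$summary$region_counts, row.names = FALSE)
  invisible(x)
}

#' DMR length distribution
#'
#' Tallies DMR lengths into `[break_i, break_{i+1})` classes; an initial
#' class below the first break and a final open class are added.
#'
#' @param dmrs A `dmr_set`.
#' @param breaks Strictly increasing break points in bp.
#' @return A `data.table` with `from`, `to`, `count`, `pct`.
#' @export
length_distribution <- function(dmrs, breaks = c(100, 200, 400, 800)) {
  if (is.unsorted(breaks, strictly = TRUE))
    stop_windmr("breaks must be strictly increasing")
  lens <- as.data.table(dmrs)[, end - start]
  edges <- unique(c(0, breaks, Inf))
  idx <- findInterval(lens, edges)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.table(from = edges[-length(edges)], to = edges[-1],
             count = counts,
             pct = if (length(lens)) 100 * counts / length(lens) else NA_real_)
}
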