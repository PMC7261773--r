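#' Tile a genome into sliding windows
#'
#' Windows `[s, min(s + size, L))` for `s = 0, step, 2*step, ...` while
#' `s < L`, per chromosome, in deterministic order.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param size Window size in bp (default 100).
#' @param step Step between window starts in bp (default 25; must be
#'   `<= size`).
#' @return A `data.table` with `chrom`, `start`, `end`.
#' @export
tile_windows <- function(chrom_lengths, size = 100, step = 25) {
  chrom_lengths <- check_chrom_lengths(chrom_lengths)
  if (size <= 0 || step <= 0) stop_windmr("size and step must be positive")
  if (step > size) stop_windmr("step must not exceed size")
  rbindlist(lapply(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    s <- seq.int(0L, L - 1L, by = as.integer(step))
    data.table(chrom = ch, start = s, end = pmin(s + as.integer(size), L))
  }))
}

#' Test sliding windows for differential methylation
#'
#' For one context, gathers the jointly covered sites of each window, skips
#' windows with fewer than `min_sites` sites (untested windows are excluded
#' from the multiple-testing family), applies the two-group Kruskal-Wallis
#' test to the per-cytosine levels of the two samples, and computes BH
#' q-values across all tested windows of the context genome-wide.
#'
#' @param pair A `methylome_pair`.
#' @param windows Window coordinates from [tile_windows()].
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param min_sites Minimum jointly covered sites per window per sample for
#'   the window to be tested (default 4).
#' @return A `data.table` of tested windows with `chrom`, `start`, `end`,
#'   `context`, `n_sites`, `mean_a`, `mean_b`, `h`, `p`, `q`.
#' @export
test_windows <- function(pair, windows, context, min_sites = 4) {
  if (!context %in% CONTEXTS)
    stop_windmr("context must be one of ", paste(CONTEXTS, collapse = ", "))
  win <- as.data.table(windows)
  size <- if (nrow(win)) max(win$end - win$start) else 0L
  step <- if (nrow(win) > 1) {
    st <- sort(unique(win[chrom == win$chrom[1], start]))
    if (length(st) > 1) min(diff(st)) else size
  } else size
  ctx <- context
  sites <- as.data.table(pair)[context == ctx,
                               .(chrom, pos, level_a, level_b)]
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      n_sites = integer(), mean_a = numeric(),
                      mean_b = numeric(), h = numeric(), p = numeric(),
                      q = numeric())
  if (!nrow(sites) || !nrow(win)) return(empty)
  # each site falls in up to ceiling(size/step) windows; enumerate candidate
  # starts and keep those that exist in the tiling
  k <- 0:(ceiling(size / step) - 1L)
  cand <- sites[, {
    ws <- (pos %/% step - rep(k, each = .N)) * step
    data.table(chrom = rep(chrom, length(k)), start = as.integer(ws),
               pos = rep(pos, length(k)),
               level_a = rep(level_a, length(k)),
               level_b = rep(level_b, length(k)))
  }]
  cand <- cand[start >= 0 & pos >= start]
  asn <- merge(cand, win, by = c("chrom", "start"))
  asn <- asn[pos < end]
  if (!nrow(asn)) return(empty)
  asn[, wid := .GRP, by = .(chrom, start)]
  meta <- unique(asn[, .(wid, chrom, start, end)])
  ms <- asn[, .(n_sites = .N, mean_a = mean(level_a),
                mean_b = mean(level_b)), by = wid]
  keep <- ms[n_sites >= min_sites, wid]
  if (!length(keep)) return(empty)
  kw <- kw_by_window(asn[wid %in% keep])
  out <- merge(merge(meta, ms, by = "wid"), kw[, .(wid, h, p)], by = "wid")
  out[, context := ctx]
  out[, q := bh_adjust(p)]
  setorder(out, chrom, start)
  out[, wid := NULL]
  setcolorder(out, c("chrom", "start", "end", "context", "n_sites",
                     "mean_a", "mean_b", "h", "p", "q"))
  out[]
}
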