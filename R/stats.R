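#' Two-group Kruskal-Wallis rank sum test
#'
#' Midranks are assigned over the pooled sample, the H statistic is computed
#' with the standard tie-correction divisor
#' `1 - sum(t^3 - t) / (N^3 - N)` over tie groups of size `t`, and the
#' p-value comes from the upper tail of the chi-square distribution with one
#' degree of freedom (two groups). When every pooled value is tied the
#' statistic is defined as `H = 0`, `p = 1`.
#'
#' @param values_a,values_b Non-empty numeric vectors (per-cytosine
#'   methylation levels of the two samples within a window).
#' @return A list with elements `h` and `p`.
#' @examples
#' kruskal_wallis_2group(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
#' @export
kruskal_wallis_2group <- function(values_a, values_b) {
  n1 <- length(values_a)
  n2 <- length(values_b)
  if (n1 == 0L || n2 == 0L)
    stop_windmr("both groups must be non-empty")
  pooled <- c(values_a, values_b)
  if (any(!is.finite(pooled)))
    stop_windmr("values must be finite")
  N <- n1 + n2
  r <- rank(pooled)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) return(list(h = 0, p = 1))
  # two-group form: H = 12 D^2 / (n1 n2 (N+1)), D the rank-sum deviation;
  # algebraically equal to the k-group formula but free of the catastrophic
  # cancellation that form suffers near H = 0 (midrank sums are exact in
  # floating point)
  D <- sum(r[seq_len(n1)]) - n1 * (N + 1) / 2
  h <- 12 * D * D / (n1 * n2 * (N + 1)) / C
  list(h = h, p = pchisq(h, df = 1, lower.tail = FALSE))
}

# vectorised two-group Kruskal-Wallis over many windows at once.
# `asn` has one row per (window, site): columns wid (integer window index),
# level_a, level_b. Returns one row per wid with n_sites, h, p.
kw_by_window <- function(asn) {
  n <- nrow(asn)
  long <- data.table(wid = rep(asn$wid, 2L),
                     grp = rep(c(1L, 2L), each = n),
                     lev = c(asn$level_a, asn$level_b))
  setorder(long, wid)
  long[, r := frankv(lev, ties.method = "average"), by = wid]
  stats <- long[, {
    N <- .N
    n1 <- sum(grp == 1L)
    D <- sum(r[grp == 1L]) - n1 * (N + 1) / 2
    tt <- tabulate(frankv(lev, ties.method = "dense"))
    C <- 1 - sum(tt^3 - tt) / (N^3 - N)
    .(n_sites = n1,
      h = if (C <= 0) 0 else 12 * D * D / (n1 * (N - n1) * (N + 1)) / C,
      tiesat = C <= 0)
  }, by = wid]
  stats[, p := fifelse(tiesat, 1, pchisq(h, df = 1, lower.tail = FALSE))]
  stats[, tiesat := NULL]
  stats[]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns BH q-values in the input order: with p-values sorted ascending,
#' `q_(i) = min over j >= i of (m * p_(j) / j)`, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop_windmr("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
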