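#' Classify genes by expression change
#'
#' A gene is `non_expressed` when its FPKM is below `min_fpkm` in both
#' samples; otherwise it is `increased` or `decreased` by the sign of its
#' log2 fold change when `fdr < fdr_alpha`, and `non_diff` otherwise. The
#' four classes partition the gene set.
#'
#' @param records Expression table (see [read_expression_table()]).
#' @param fdr_alpha Differential-expression FDR threshold (default 0.05).
#' @param min_fpkm Expression floor (default 1 FPKM).
#' @return A `data.table` with `gene_id`, `class`, `log2fc`, `fdr`.
#' @export
classify_expression <- function(records, fdr_alpha = 0.05, min_fpkm = 1) {
  dt <- as.data.table(records)
  cls <- ifelse(dt$fpkm_a < min_fpkm & dt$fpkm_b < min_fpkm, "non_expressed",
         ifelse(dt$fdr < fdr_alpha & dt$log2fc > 0, "increased",
         ifelse(dt$fdr < fdr_alpha & dt$log2fc < 0, "decreased",
                "non_diff")))
  data.table(gene_id = dt$gene_id, class = cls, log2fc = dt$log2fc,
             fdr = dt$fdr)
}

#' Group genes by the DMR content of a gene region
#'
#' For the chosen region (`upstream`, `gene_body`, `downstream`, or
#' `whole_gene` = the union of the three), each gene is assigned `hyper`,
#' `hypo`, `both` (at least one DMR of each trend) or `none` from the trends
#' of the DMRs overlapping that region.
#'
#' @param genes Character vector of gene ids (defines the `none` universe).
#' @param annotations The `annotations` table of [annotate_dmrs()] (or the
#'   `dmr_annotation` object itself).
#' @param region One of `"upstream"`, `"gene_body"`, `"downstream"`,
#'   `"whole_gene"`.
#' @return A `data.table` with `gene_id`, `region`, `group`.
#' @export
group_by_dmr <- function(genes, annotations, region = "whole_gene") {
  if (!region %in% c(REGIONS, "whole_gene"))
    stop_windmr("unknown region '", region, "'")
  if (inherits(annotations, "dmr_annotation"))
    annotations <- annotations$annotations
  ann <- as.data.table(annotations)
  if (region != "whole_gene") {
    reg <- region
    ann <- ann[ann$region == reg]
  }
  grp <- ann[, .(group = {
    tr <- unique(trend)
    if (length(tr) > 1) "both" else tr
  }), by = gene_id]
  reg_val <- region
  out <- data.table(gene_id = genes)
  out <- merge(out, grp, by = "gene_id", all.x = TRUE, sort = FALSE)
  out[is.na(group), group := "none"]
  out[, region := reg_val]
  setcolorder(out, c("gene_id", "region", "group"))
  out[]
}

#' Compare expression fold changes across DMR groups
#'
#' Reproduces the gene-body methylation / expression association analysis:
#' among differentially expressed genes with at least `min_abs_fc`-fold
#' change (increased and decreased classes treated separately), genes are
#' grouped per region by their DMR content (`hyper`/`hypo`/`both`/`none`),
#' a seeded random control group is drawn from the same DEG set, log2
#' fold-change distributions are summarised, and all group pairs are
#' compared with two-sided Wilcoxon rank-sum tests, BH-corrected within each
#' (direction, region) family.
#'
#' @param classes Output of [classify_expression()].
#' @param annotations A `dmr_annotation` (or its `annotations` table).
#' @param min_abs_fc Minimum absolute linear fold change for a DEG to enter
#'   (default 4, i.e. `|log2fc| >= 2`).
#' @param n_random Size of the random control group; default the size of
#'   the largest non-empty DMR group.
#' @param seed Seed for the random control draw.
#' @param regions Regions to analyse.
#' @return A list of class `foldchange_comparison` with `summary` (per
#'   direction x region x group: `n`, `median`, `q25`, `q75`) and `tests`
#'   (pairwise rank-sum p-values with BH-adjusted `q`).
#' @export
foldchange_comparison <- function(classes, annotations, min_abs_fc = 4,
                                  n_random = NULL, seed = 1,
                                  regions = c(REGIONS, "whole_gene")) {
  cls <- as.data.table(classes)
  lfc_cut <- log2(min_abs_fc)
  summaries <- list()
  tests <- list()
  for (direction in c("increased", "decreased")) {
    degs <- cls[class == direction & abs(log2fc) >= lfc_cut]
    for (reg in regions) {
      grp <- group_by_dmr(degs$gene_id, annotations, reg)
      d <- merge(degs, grp, by = "gene_id")
      groups <- split(d$log2fc, factor(d$group,
                                       c("hyper", "hypo", "both", "none")))
      nr <- n_random %||% max(1L, max(lengths(
        groups[c("hyper", "hypo", "both")])))
      if (nrow(d)) {
        rnd <- with_seed(seed,
                         sample(d$log2fc, size = min(nr, nrow(d))))
        groups$random <- rnd
      } else groups$random <- numeric()
      sm <- rbindlist(lapply(names(groups), function(g) {
        v <- groups[[g]]
        data.table(direction = direction, region = reg, group = g,
                   n = length(v),
                   median = if (length(v)) median(v) else NA_real_,
                   q25 = if (length(v)) quantile(v, 0.25, names = FALSE)
                         else NA_real_,
                   q75 = if (length(v)) quantile(v, 0.75, names = FALSE)
                         else NA_real_)
      }))
      summaries[[length(summaries) + 1L]] <- sm
      gn <- names(groups)
      prs <- if (length(gn) > 1) utils::combn(gn, 2, simplify = FALSE)
             else list()
      tst <- rbindlist(lapply(prs, function(pr) {
        v1 <- groups[[pr[1]]]
        v2 <- groups[[pr[2]]]
        p <- if (length(v1) >= 2 && length(v2) >= 2)
          suppressWarnings(wilcox.test(v1, v2, exact = FALSE)$p.value)
        else NA_real_
        data.table(direction = direction, region = reg,
                   group1 = pr[1], group2 = pr[2],
                   n1 = length(v1), n2 = length(v2), p = p)
      }))
      if (nrow(tst)) {
        ok <- !is.na(tst$p)
        tst[, q := NA_real_]
        if (any(ok)) tst[ok, q := bh_adjust(tst$p[ok])]
        tests[[length(tests) + 1L]] <- tst
      }
    }
  }
  out <- list(summary = rbindlist(summaries),
              tests = rbindlist(tests),
              min_abs_fc = min_abs_fc, seed = seed)
  class(out) <- "foldchange_comparison"
  out
}

#' @export
print.foldchange_comparison <- function(x, ...) {
  cat(sprintf(
    "log2 fold-change by DMR group (DEGs with >= %s-fold change)\n",
    x$min_abs_fc))
  print(x$summary[n > 0], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Percentage of DMR-containing genes per expression class
#'
#' For each expression class, the percentage of genes whose whole gene
#' region (body plus flanks) overlaps at least one DMR.
#'
#' @param classes Output of [classify_expression()].
#' @param annotations A `dmr_annotation` (or its `annotations` table).
#' @return A `data.table` with `class`, `n_genes`, `n_with_dmr`,
#'   `pct_dmr_genes` (NA for empty classes).
#' @export
dmr_gene_percentages <- function(classes, annotations) {
  cls <- as.data.table(classes)
  grp <- group_by_dmr(cls$gene_id, annotations, "whole_gene")
  d <- merge(cls, grp, by = "gene_id")
  lv <- c("increased", "decreased", "non_diff", "non_expressed")
  out <- d[, .(n_genes = .N, n_with_dmr = sum(group != "none")),
           by = .(class = factor(class, lv))]
  out <- out[data.table(class = factor(lv, lv)), on = "class"]
  out[is.na(n_genes), `:=`(n_genes = 0L, n_with_dmr = 0L)]
  out[, pct_dmr_genes := fifelse(n_genes > 0, 100 * n_with_dmr / n_genes,
                                 NA_real_)]
  out[, class := as.character(class)]
  out[]
}
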