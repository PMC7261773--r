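#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic paired-methylome
#' generator. Defaults emulate the statistical structure of a
#' diploid/autotetraploid grapevine WGBS comparison: context-stratified mean
#' methylation levels around 0.34 (CG) / 0.30 (CHG) / 0.16 (CHH), ~12x
#' Poisson coverage per sample, sparse planted DMRs concentrated in the CHH
#' context, and expression changes coupled to gene-body DMR direction
#' (body hypo-DMR -> expression up, body hyper-DMR -> down).
#'
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @param chrom_lengths Named vector of chromosome lengths (default two 1-Mb
#'   chromosomes).
#' @param gc_fraction Genome G+C fraction (default 0.35, grape-like).
#' @param context_means Named mean methylation levels per context.
#' @param level_concentration Beta concentration of regional true levels
#'   (larger = less dispersed; default 6).
#' @param segment_length Mean length in bp of the piecewise-constant
#'   methylation segments emulating spatial autocorrelation (default 300).
#' @param coverage_mean Poisson mean read depth per site per sample
#'   (default 12).
#' @param n_dmrs Named count of planted DMRs per context (default 200 CHH
#'   only).
#' @param dmr_delta Methylation-level shift inside planted DMRs (default
#'   0.3; sign per-DMR).
#' @param dmr_length_range Planted DMR length range in bp (default
#'   100-400).
#' @param dmr_min_sites Minimum context cytosines a planted DMR must cover
#'   (default 8).
#' @param frac_dmrs_body,frac_dmrs_flank Fraction of planted DMRs placed
#'   inside gene bodies / gene flanks (defaults 0.4 and 0.15; the rest is
#'   intergenic).
#' @param n_genes Number of non-overlapping genes (default 250,
#'   grape-like density at 2 Mb).
#' @param gene_length_range Gene length range in bp (default 1500-2500).
#' @param flank Flank width used for placement bookkeeping (default 2000).
#' @param nonexpr_fraction Fraction of background genes not expressed
#'   (default 0.2).
#' @param deg_fraction Fraction of background expressed genes that are DEGs
#'   (default 0.3).
#' @param frac_small_deg Fraction of background DEGs drawn below the 4-fold
#'   threshold (default 0.25), so downstream fold-change filters bind.
#' @param deg_lfc_base,deg_lfc_shape,deg_lfc_rate Large-DEG |log2fc| =
#'   base + Gamma(shape, rate) (defaults 2.1 + Gamma(4, 8)).
#' @param small_lfc_range |log2fc| range of small DEGs (default 0.5-2).
#' @param couple_prob Probability that a gene with a planted body DMR
#'   becomes a DEG in the coupled direction (default 0.8).
#' @param couple_lfc Additional log2fc increment for coupled genes (default
#'   +1 for body-hypo, -1 for body-hyper).
#' @param lfc_noise_sd SD of measurement noise on realised log2fc (default
#'   0.15).
#' @param fpkm_meanlog,fpkm_sdlog Log-normal baseline FPKM parameters
#'   (defaults 2 and 1).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                              gc_fraction = 0.35,
                              context_means = c(CG = 0.34, CHG = 0.30,
                                                CHH = 0.16),
                              level_concentration = 6,
                              segment_length = 300,
                              coverage_mean = 12,
                              n_dmrs = c(CG = 0, CHG = 0, CHH = 200),
                              dmr_delta = 0.3,
                              dmr_length_range = c(100, 400),
                              dmr_min_sites = 8,
                              frac_dmrs_body = 0.4,
                              frac_dmrs_flank = 0.15,
                              n_genes = 250,
                              gene_length_range = c(1500, 2500),
                              flank = 2000,
                              nonexpr_fraction = 0.2,
                              deg_fraction = 0.3,
                              frac_small_deg = 0.25,
                              deg_lfc_base = 2.1,
                              deg_lfc_shape = 4,
                              deg_lfc_rate = 8,
                              small_lfc_range = c(0.5, 2),
                              couple_prob = 0.8,
                              couple_lfc = 1,
                              lfc_noise_sd = 0.15,
                              fpkm_meanlog = 2,
                              fpkm_sdlog = 1) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_windmr("a scalar integer seed is mandatory")
  check_chrom_lengths(chrom_lengths)
  probs <- c(gc_fraction, context_means, nonexpr_fraction, deg_fraction,
             frac_small_deg, couple_prob, frac_dmrs_body, frac_dmrs_flank)
  if (any(probs < 0 | probs > 1))
    stop_windmr("all probabilities/fractions must lie in [0, 1]")
  if (frac_dmrs_body + frac_dmrs_flank > 1)
    stop_windmr("frac_dmrs_body + frac_dmrs_flank must not exceed 1")
  if (!all(CONTEXTS %in% names(context_means)) ||
      !all(CONTEXTS %in% names(n_dmrs)))
    stop_windmr("context_means and n_dmrs must name CG, CHG and CHH")
  if (dmr_delta < 0 || dmr_delta > 1)
    stop_windmr("dmr_delta must lie in [0, 1]")
  if (coverage_mean <= 0 || level_concentration <= 0 || segment_length <= 0)
    stop_windmr("coverage_mean, level_concentration and segment_length must be positive")
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic methylome configuration\n")
  cat("  genome:", length(x$chrom_lengths), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp, GC",
      x$gc_fraction, "\n")
  cat("  context means:",
      paste(names(x$context_means), x$context_means, collapse = ", "),
      "\n")
  cat("  coverage mean:", x$coverage_mean, " planted DMRs:",
      paste(names(x$n_dmrs), x$n_dmrs, collapse = ", "),
      " delta:", x$dmr_delta, "\n")
  cat("  genes:", x$n_genes, " coupling: prob", x$couple_prob,
      "lfc", x$couple_lfc, "\n")
  invisible(x)
}

# trinucleotide context of every cytosine on both strands of one sequence
# (plus strand: C at i with seq[i+1:i+2]; minus strand: G at i, read on the
# reverse complement). Positions 0-based.
context_catalog_chrom <- function(bases, chrom) {
  L <- length(bases)
  ispC <- which(bases == "C")
  ispG <- which(bases == "G")
  classify_plus <- function(i) {
    b1 <- if (i + 1 <= L) bases[i + 1] else ""
    b2 <- if (i + 2 <= L) bases[i + 2] else ""
    if (b1 == "G") "CG" else if (b2 == "G") "CHG" else "CHH"
  }
  classify_minus <- function(i) {
    b1 <- if (i - 1 >= 1) bases[i - 1] else ""
    b2 <- if (i - 2 >= 1) bases[i - 2] else ""
    if (b1 == "C") "CG" else if (b2 == "C") "CHG" else "CHH"
  }
  ctx_p <- vapply(ispC, classify_plus, "")
  ctx_m <- vapply(ispG, classify_minus, "")
  rbind(
    data.table(chrom = chrom, pos = ispC - 1L, strand = "+", context = ctx_p),
    data.table(chrom = chrom, pos = ispG - 1L, strand = "-", context = ctx_m))
}

#' Generate a random genome and its cytosine context catalog
#'
#' Draws an i.i.d. sequence at the configured G+C fraction and assigns every
#' cytosine on both strands its CG/CHG/CHH class from the local
#' trinucleotide (a plus-strand cytosine followed by G is CG, by H then G is
#' CHG, else CHH; minus-strand sites mirror through the reverse complement).
#' Chromosome-terminal cytosines with a truncated trinucleotide default to
#' CHH.
#'
#' @param config A [simulation_config()].
#' @return A list with `sequences` (named character vector of chromosome
#'   sequences) and `catalog` (`data.table` of `chrom`, `pos`, `strand`,
#'   `context`, sorted).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    gc <- config$gc_fraction
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- lapply(names(config$chrom_lengths), function(ch) {
      sample(names(p), config$chrom_lengths[[ch]], replace = TRUE, prob = p)
    })
    names(seqs) <- names(config$chrom_lengths)
    catalog <- rbindlist(lapply(names(seqs), function(ch)
      context_catalog_chrom(seqs[[ch]], ch)))
    setorder(catalog, chrom, pos, strand)
    list(sequences = vapply(seqs, paste, "", collapse = ""),
         catalog = catalog[])
  })
}

# lay out n non-overlapping genes on alternating strands: the genome is cut
# into equal slots, one gene per slot at a random offset
place_genes <- function(config) {
  lens <- config$chrom_lengths
  n_per <- round(config$n_genes * lens / sum(lens))
  n_per[length(n_per)] <- config$n_genes - sum(head(n_per, -1))
  genes <- rbindlist(lapply(seq_along(lens), function(ci) {
    ch <- names(lens)[ci]
    n <- n_per[ci]
    if (n <= 0) return(NULL)
    slot <- floor(lens[[ci]] / n)
    glen <- sample(seq(config$gene_length_range[1],
                       config$gene_length_range[2]), n, replace = TRUE)
    glen <- pmin(glen, slot - 2L)
    offset <- floor(runif(n) * (slot - glen))
    start <- as.integer((seq_len(n) - 1L) * slot + offset)
    data.table(chrom = ch, start = start, end = as.integer(start + glen),
               strand = rep_len(c("+", "-"), n))
  }))
  setorder(genes, chrom, start)
  genes[, gene_id := sprintf("g%04d", .I)]
  setcolorder(genes, c("gene_id", "chrom", "start", "end", "strand"))
  genes[]
}

# plant DMR intervals: a fraction inside distinct gene bodies, a fraction in
# gene flanks, the rest intergenic; each must cover >= dmr_min_sites
# cytosines of its context and stay clear of other planted DMRs
plant_dmrs <- function(config, catalog, genes) {
  out <- list()
  taken <- data.table(chrom = character(), start = integer(),
                      end = integer())
  ctx_sites <- split(catalog, by = "context")
  regions <- gene_regions(genes, config$flank)
  count_sites <- function(ctx, ch, s, e) {
    cs <- ctx_sites[[ctx]]
    if (is.null(cs)) return(0L)
    cs[chrom == ch & pos >= s & pos < e, .N]
  }
  clear_of <- function(ch, s, e, pad = 500L) {
    !nrow(taken[chrom == ch & start < e + pad & end > s - pad])
  }
  gene_pool <- genes[sample(nrow(genes))]
  gi <- 0L
  for (ctx in CONTEXTS) {
    n <- config$n_dmrs[[ctx]]
    if (n == 0) next
    n_body <- round(n * config$frac_dmrs_body)
    n_flank <- round(n * config$frac_dmrs_flank)
    kinds <- c(rep("gene_body", n_body), rep("flank", n_flank),
               rep("intergenic", n - n_body - n_flank))
    for (kind in kinds) {
      placed <- FALSE
      for (try in 1:200) {
        len <- sample(seq(config$dmr_length_range[1],
                          config$dmr_length_range[2]), 1)
        if (kind == "gene_body") {
          if (gi >= nrow(gene_pool))
            stop_windmr("not enough genes to host planted body DMRs")
          g <- gene_pool[gi + 1L]
          if (g$end - g$start <= len) { gi <- gi + 1L; next }
          s <- g$start + sample.int(g$end - g$start - len, 1)
          ch <- g$chrom
          gene <- g$gene_id
        } else if (kind == "flank") {
          if (gi >= nrow(gene_pool))
            stop_windmr("not enough genes to host planted flank DMRs")
          g <- gene_pool[gi + 1L]
          fl <- regions[gene_id == g$gene_id &
                          region %in% c("upstream", "downstream")]
          fl <- fl[sample(nrow(fl), 1)]
          if (fl$end - fl$start <= len) { gi <- gi + 1L; next }
          s <- fl$start + sample.int(fl$end - fl$start - len, 1)
          ch <- fl$chrom
          # reject flank placements that bleed into any gene body
          if (nrow(genes[chrom == ch & start < s + len & end > s])) next
          gene <- g$gene_id
        } else {
          ch <- sample(names(config$chrom_lengths), 1,
                       prob = config$chrom_lengths)
          s <- sample.int(config$chrom_lengths[[ch]] - len, 1)
          # intergenic: outside every gene region (body + flanks)
          if (nrow(regions[chrom == ch & start < s + len & end > s])) next
          gene <- NA_character_
        }
        if (!clear_of(ch, s, s + len)) next
        if (count_sites(ctx, ch, s, s + len) < config$dmr_min_sites) next
        trend <- if (runif(1) < 0.5) "hyper" else "hypo"
        out[[length(out) + 1L]] <- data.table(
          chrom = ch, start = as.integer(s), end = as.integer(s + len),
          context = ctx, trend = trend, delta = config$dmr_delta,
          placement = kind, gene_id = gene)
        taken <- rbind(taken,
                       data.table(chrom = ch, start = as.integer(s),
                                  end = as.integer(s + len)))
        if (kind %in% c("gene_body", "flank")) gi <- gi + 1L
        placed <- TRUE
        break
      }
      if (!placed)
        stop_windmr("could not place a planted ", ctx, " DMR (", kind,
                    ") after bounded retries")
    }
  }
  if (!length(out))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      trend = character(), delta = numeric(),
                      placement = character(), gene_id = character()))
  truth <- rbindlist(out)
  setorder(truth, chrom, start)
  truth[]
}

#' Simulate a paired methylome with planted DMRs
#'
#' True methylation levels are piecewise constant over random segments
#' (mean length `segment_length`), drawn per segment and context from a Beta
#' distribution with the configured context mean and concentration — a
#' simple model of the spatial autocorrelation of plant methylomes. Sample B
#' inherits sample A's true levels except inside planted DMRs, where the
#' level shifts by the DMR's signed delta (clipped to `[0, 1]`). Read
#' coverage is Poisson per site and sample; methylated counts are binomial,
#' giving beta-binomial observed levels.
#'
#' @param config A [simulation_config()].
#' @param catalog Cytosine catalog from [generate_genome()].
#' @param genes Optional gene table from the internal layout step; when
#'   supplied, the configured fractions of planted DMRs are placed in gene
#'   bodies and flanks (used for expression coupling). Without it all
#'   planted DMRs are placed uniformly.
#' @return A list with `sample_a`, `sample_b` (cytosine site tables) and
#'   `truth` (planted DMR table with context, trend, delta, placement).
#' @export
simulate_methylome_pair <- function(config, catalog, genes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!nrow(catalog)) stop_windmr("catalog is empty")
  with_seed(config$seed + 1L, {
    if (is.null(genes)) {
      cfg2 <- config
      cfg2$frac_dmrs_body <- 0
      cfg2$frac_dmrs_flank <- 0
      genes0 <- data.table(gene_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character())
      truth <- plant_dmrs(cfg2, catalog, genes0)
    } else {
      truth <- plant_dmrs(config, catalog, genes)
    }
    sites <- copy(catalog)
    # segment boundaries: iid uniform lengths, mean = segment_length
    rng <- c(0.5, 1.5) * config$segment_length
    seg_map <- lapply(names(config$chrom_lengths), function(ch) {
      L <- config$chrom_lengths[[ch]]
      n_seg <- ceiling(L / rng[1]) + 1L
      lens <- runif(n_seg, rng[1], rng[2])
      bounds <- cumsum(lens)
      bounds <- bounds[bounds < L]
      c(0, bounds, L)
    })
    names(seg_map) <- names(config$chrom_lengths)
    sites[, seg := findInterval(pos, seg_map[[chrom[1]]]), by = chrom]
    # per segment x context true level
    key <- unique(sites[, .(chrom, seg, context)])
    m <- config$context_means[key$context]
    conc <- config$level_concentration
    key[, level := rbeta(.N, m * conc, (1 - m) * conc)]
    sites <- merge(sites, key, by = c("chrom", "seg", "context"),
                   sort = FALSE)
    setorder(sites, chrom, pos, strand)
    level_a <- sites$level
    level_b <- level_a
    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        idx <- sites[, which(chrom == truth$chrom[i] &
                               pos >= truth$start[i] &
                               pos < truth$end[i] &
                               context == truth$context[i])]
        shift_by <- if (truth$trend[i] == "hyper") truth$delta[i]
                    else -truth$delta[i]
        level_b[idx] <- pmin(1, pmax(0, level_a[idx] + shift_by))
      }
    }
    n <- nrow(sites)
    mk_sample <- function(lv) {
      cov <- rpois(n, config$coverage_mean)
      meth <- rbinom(n, cov, lv)
      dt <- data.table(chrom = sites$chrom, pos = sites$pos,
                       strand = sites$strand, n_meth = meth,
                       n_unmeth = cov - meth, context = sites$context)
      setorder(dt, chrom, pos, strand)
      dt[]
    }
    sample_a <- mk_sample(level_a)
    sample_b <- mk_sample(level_b)
    list(sample_a = sample_a, sample_b = sample_b, truth = truth)
  })
}

#' Simulate gene expression coupled to planted gene-body DMRs
#'
#' Lays the configured genes over the genome (when not supplied), draws
#' log-normal baseline FPKM, assigns a background fraction of non-expressed
#' genes and DEGs, and couples expression to the planted methylome truth:
#' a gene whose body hosts a planted hypo-DMR becomes, with probability
#' `couple_prob`, an increased DEG whose |log2fc| carries an additional
#' `couple_lfc` increment (hyper-DMR genes mirror this downwards). Reported
#' FDRs are generated (small for DEGs, uniform above the threshold for the
#' rest); differential-expression testing itself is out of scope.
#'
#' @param config A [simulation_config()].
#' @param genes Gene table (from the experiment wrapper).
#' @param truth Planted DMR table from [simulate_methylome_pair()].
#' @return A list with `expression` (a table readable by
#'   [read_expression_table()]) and `gene_truth` (per-gene class, true
#'   log2fc, coupling label).
#' @export
simulate_genes_expression <- function(config, genes, truth) {
  stopifnot(inherits(config, "simulation_config"))
  g <- as.data.table(genes)
  with_seed(config$seed + 2L, {
    n <- nrow(g)
    body <- truth[placement == "gene_body" & !is.na(gene_id)]
    body_trend <- body[, .(trend = if (uniqueN(trend) > 1) "both"
                           else trend[1]), by = gene_id]
    gt <- data.table(gene_id = g$gene_id)
    gt <- merge(gt, body_trend, by = "gene_id", all.x = TRUE, sort = FALSE)
    setnames(gt, "trend", "body_dmr")
    big_lfc <- function(k) config$deg_lfc_base +
      rgamma(k, shape = config$deg_lfc_shape, rate = config$deg_lfc_rate)
    u <- runif(n)
    coupled <- !is.na(gt$body_dmr) & gt$body_dmr %in% c("hyper", "hypo") &
      u < config$couple_prob
    class_true <- character(n)
    lfc_true <- numeric(n)
    dirn <- ifelse(gt$body_dmr == "hypo", 1, -1)
    class_true[coupled] <- ifelse(dirn[coupled] > 0, "increased",
                                  "decreased")
    lfc_true[coupled] <- dirn[coupled] *
      (big_lfc(sum(coupled)) + config$couple_lfc)
    bg <- !coupled
    u2 <- runif(n)
    nonexpr <- bg & u2 < config$nonexpr_fraction
    deg <- bg & !nonexpr &
      u2 < config$nonexpr_fraction +
        (1 - config$nonexpr_fraction) * config$deg_fraction
    nondiff <- bg & !nonexpr & !deg
    class_true[nonexpr] <- "non_expressed"
    k <- sum(deg)
    if (k) {
      sign_deg <- sample(c(-1, 1), k, replace = TRUE)
      small <- runif(k) < config$frac_small_deg
      mag <- ifelse(small,
                    runif(k, config$small_lfc_range[1],
                          config$small_lfc_range[2]),
                    big_lfc(k))
      lfc_true[deg] <- sign_deg * mag
      class_true[deg] <- ifelse(sign_deg > 0, "increased", "decreased")
    }
    lfc_true[nondiff] <- rnorm(sum(nondiff), 0, 0.4)
    class_true[nondiff] <- "non_diff"
    # observed table
    fpkm_a <- numeric(n)
    fpkm_a[!nonexpr] <- pmax(1.05, rlnorm(sum(!nonexpr),
                                          config$fpkm_meanlog,
                                          config$fpkm_sdlog))
    fpkm_a[nonexpr] <- runif(sum(nonexpr), 0.01, 0.8)
    lfc_obs <- lfc_true + rnorm(n, 0, config$lfc_noise_sd)
    fpkm_b <- fpkm_a * 2^lfc_obs
    fpkm_b[nonexpr] <- runif(sum(nonexpr), 0.01, 0.8)
    lfc_obs[nonexpr] <- log2(fpkm_b[nonexpr] / fpkm_a[nonexpr])
    fdr <- runif(n, 0.1, 1)
    is_deg <- coupled | deg
    fdr[is_deg] <- runif(sum(is_deg), 1e-6, 0.04)
    expression <- data.table(gene_id = g$gene_id, fpkm_a = fpkm_a,
                             fpkm_b = fpkm_b, log2fc = lfc_obs, fdr = fdr)
    gene_truth <- data.table(gene_id = g$gene_id,
                             class_true = class_true,
                             lfc_true = lfc_true,
                             body_dmr = gt$body_dmr,
                             coupled = coupled)
    list(expression = expression[], gene_truth = gene_truth[])
  })
}

#' Run the whole synthetic-experiment generator
#'
#' Generates genome, genes, paired methylome with planted DMRs, and a coupled
#' expression table; optionally writes everything to disk in the standard
#' formats (FASTA, two cytosine reports, GFF3, expression TSV, truth TSVs).
#' Identical config (including seed) gives byte-identical outputs.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional output directory.
#' @return A list with `genome`, `genes`, `sample_a`, `sample_b`,
#'   `expression`, `truth` (planted DMRs) and `gene_truth`, plus `paths`
#'   when `outdir` is given.
#' @export
simulate_methylome_experiment <- function(config, outdir = NULL) {
  genome <- generate_genome(config)
  genes <- with_seed(config$seed + 3L, place_genes(config))
  meth <- simulate_methylome_pair(config, genome$catalog, genes)
  expr <- simulate_genes_expression(config, genes, meth$truth)
  out <- list(genome = genome, genes = genes,
              sample_a = meth$sample_a, sample_b = meth$sample_b,
              expression = expr$expression, truth = meth$truth,
              gene_truth = expr$gene_truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(outdir, "genome.fa"),
      report_a = file.path(outdir, "sample_a.cx_report.txt"),
      report_b = file.path(outdir, "sample_b.cx_report.txt"),
      gff = file.path(outdir, "genes.gff3"),
      expression = file.path(outdir, "expression.tsv"),
      truth_dmrs = file.path(outdir, "truth_dmrs.tsv"),
      truth_genes = file.path(outdir, "truth_genes.tsv"))
    dna <- Biostrings::DNAStringSet(genome$sequences)
    Biostrings::writeXStringSet(dna, paths$fasta)
    write_cytosine_report(out$sample_a, paths$report_a)
    write_cytosine_report(out$sample_b, paths$report_b)
    write_gene_models(genes, paths$gff)
    write_expression_table(out$expression, paths$expression)
    write_tsv(out$truth, paths$truth_dmrs)
    write_tsv(out$gene_truth, paths$truth_genes)
    out$paths <- paths
  }
  out
}

#' Evaluate recovery of planted DMRs
#'
#' A planted DMR is recovered when a called DMR of the same context and
#' trend overlaps at least `min_overlap_fraction` of the planted interval.
#' With `reciprocal = FALSE` (the default) a called DMR is a true positive
#' on any same context/trend overlap (>= 1 bp); with `reciprocal = TRUE`
#' the matching is enforced on both sides, each interval judged on its own
#' length: a call is a true positive only when at least
#' `min_overlap_fraction` of the *call* lies inside a planted DMR. A merged
#' call list typically contains short (single-window) fragments inside long
#' planted regions, so requiring a short call to cover half of a long
#' planted interval would misread fragments as false positives; the
#' own-side rule counts them correctly while still rejecting calls that
#' are mostly outside any planted region.
#'
#' @param called_dmrs A `dmr_set`.
#' @param truth Planted DMR table from the simulator.
#' @param min_overlap_fraction Required overlap fraction (default 0.5).
#' @param reciprocal Enforce the fraction on the called side too (default
#'   FALSE).
#' @return A list with `sensitivity`, `precision`, `n_planted`, `n_called`,
#'   and a `per_context` table.
#' @export
evaluate_recovery <- function(called_dmrs, truth,
                              min_overlap_fraction = 0.5,
                              reciprocal = FALSE) {
  cd <- as.data.table(called_dmrs)
  tr <- as.data.table(truth)
  match_flags <- function(a, b, frac_on_a, frac_on_b) {
    # for each row of a: any row of b, same chrom/context/trend, whose
    # overlap covers frac_on_a of a (and frac_on_b of b if not NA)
    if (!nrow(a)) return(logical())
    if (!nrow(b)) return(rep(FALSE, nrow(a)))
    ga <- GenomicRanges::GRanges(paste(a$chrom, a$context, a$trend,
                                       sep = "|"),
                                 IRanges::IRanges(a$start + 1L, a$end))
    gb <- GenomicRanges::GRanges(paste(b$chrom, b$context, b$trend,
                                       sep = "|"),
                                 IRanges::IRanges(b$start + 1L, b$end))
    GenomeInfoDb::seqlevels(ga) <- union(GenomeInfoDb::seqlevels(ga),
                                         GenomeInfoDb::seqlevels(gb))
    GenomeInfoDb::seqlevels(gb) <- GenomeInfoDb::seqlevels(ga)
    hits <- GenomicRanges::findOverlaps(ga, gb)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(a$end[qh], b$end[sh]) - pmax(a$start[qh], b$start[sh])
    ok <- ov >= frac_on_a * (a$end[qh] - a$start[qh])
    if (!is.na(frac_on_b))
      ok <- ok & ov >= frac_on_b * (b$end[sh] - b$start[sh])
    flags <- rep(FALSE, nrow(a))
    flags[unique(qh[ok])] <- TRUE
    flags
  }
  tr_rec <- match_flags(tr, cd, min_overlap_fraction, NA_real_)
  cd_tp <- match_flags(cd, tr,
                       if (reciprocal) min_overlap_fraction else 0,
                       NA_real_)
  per <- rbindlist(lapply(CONTEXTS, function(ctx) {
    it <- tr$context == ctx
    ic <- cd$context == ctx
    data.table(context = ctx, n_planted = sum(it),
               n_recovered = sum(tr_rec[it]), n_called = sum(ic),
               n_tp = sum(cd_tp[ic]),
               sensitivity = if (sum(it)) sum(tr_rec[it]) / sum(it)
                             else NA_real_,
               precision = if (sum(ic)) sum(cd_tp[ic]) / sum(ic)
                           else NA_real_)
  }))
  list(sensitivity = if (nrow(tr)) mean(tr_rec) else NA_real_,
       precision = if (nrow(cd)) mean(cd_tp) else NA_real_,
       n_planted = nrow(tr), n_called = nrow(cd),
       per_context = per[])
}
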