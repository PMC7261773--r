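#' Pipeline configuration
#'
#' Collects input paths and analysis thresholds for [run_pipeline()].
#' Defaults are the standard parameters of the diploid/autotetraploid
#' comparison: joint coverage of 3 reads, 100-bp windows at 25-bp steps,
#' q < 0.05, region fold-change threshold 1.2, 2-kb flanks, |fold| >= 4 for
#' the association analysis, FPKM < 1 as not expressed.
#'
#' @param report_a,report_b Paths to the two cytosine reports (A = the
#'   reference/diploid-analog sample, B = the comparison/tetraploid-analog
#'   sample; trends are B over A).
#' @param gff Path to the GFF3 gene models.
#' @param expression Path to the expression table.
#' @param outdir Output directory.
#' @param chrom_lengths Named chromosome lengths; alternatively give
#'   `fasta` and lengths are taken from the sequences.
#' @param fasta Optional genome FASTA used for chromosome lengths.
#' @param min_coverage Joint coverage threshold (default 3).
#' @param window_size,step Sliding-window geometry (default 100/25 bp).
#' @param min_sites Minimum sites per tested window (default 4).
#' @param alpha DMR significance level on q-values (default 0.05).
#' @param fc_threshold Region fold-change filter (default 1.2).
#' @param merge_gap Maximum gap for same-trend merging (default 0).
#' @param flank Gene flank width (default 2000 bp).
#' @param min_abs_fc Fold-change floor of the association analysis
#'   (default 4).
#' @param min_fpkm Expression floor (default 1 FPKM).
#' @param fdr_alpha Differential-expression FDR threshold (default 0.05).
#' @param contexts Contexts to test (default all three).
#' @param bin_size Profile bin width (default 50000 bp).
#' @param seed Seed for the association random control.
#' @param write_windows Also write the per-window statistics table
#'   (default FALSE; it is large).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(report_a, report_b, gff, expression, outdir,
                            chrom_lengths = NULL, fasta = NULL,
                            min_coverage = 3, window_size = 100, step = 25,
                            min_sites = 4, alpha = 0.05, fc_threshold = 1.2,
                            merge_gap = 0, flank = 2000, min_abs_fc = 4,
                            min_fpkm = 1, fdr_alpha = 0.05,
                            contexts = CONTEXTS, bin_size = 50000,
                            seed = 1, write_windows = FALSE) {
  cfg <- as.list(environment())
  bad <- setdiff(contexts, CONTEXTS)
  if (length(bad))
    stop_windmr("unknown context token(s): ", paste(bad, collapse = ", "))
  if (is.null(chrom_lengths) && is.null(fasta))
    stop_windmr("either chrom_lengths or fasta must be given")
  if (!is.null(chrom_lengths)) check_chrom_lengths(chrom_lengths)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `chrom_lengths` is a
#' mapping of chromosome name to length.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$chrom_lengths))
    y$chrom_lengths <- unlist(y$chrom_lengths)
  do.call(pipeline_config, y)
}

provenance <- function(config) {
  # fingerprint the analysis, not where it is written
  cfg <- config[setdiff(names(config), "outdir")]
  c(paste0("windmr ", as.character(utils::packageVersion("windmr")),
           "; config_hash=", config_hash(cfg),
           "; seed=", config$seed))
}

#' Run the full comparison pipeline
#'
#' Executes the stages in order — read inputs, profile the methylome pair,
#' call/merge/annotate DMRs per context, associate DMR groups with
#' expression — writing every result table under `config$outdir` with a
#' provenance header (package version, configuration hash, seed). A failing
#' stage removes the partial outputs of this run before rethrowing.
#' Re-running with identical inputs and configuration reproduces identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a result bundle: `pair`, `mc_a`, `mc_b`, `profiles`,
#'   `correlations`, `divergence`, `windows`, `dmrs_premerge`, `dmrs`,
#'   `annotation`, `classes`, `association`, `percentages`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("report_a", "report_b", "gff", "expression")) {
    if (!file.exists(config[[f]]))
      stop_windmr("missing input: ", f, " (", config[[f]], ")")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance(config)
  created <- character()
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  emit <- function(writer, obj, name, ...) {
    path <- file.path(config$outdir, name)
    writer(obj, path, ...)
    created <<- c(created, path)
    note("wrote ", name)
    path
  }
  res <- tryCatch({
    note(hdr)
    note("parameters: min_coverage=", config$min_coverage,
         " window=", config$window_size, "/", config$step,
         " min_sites=", config$min_sites, " alpha=", config$alpha,
         " fc_threshold=", config$fc_threshold,
         " flank=", config$flank, " contexts=",
         paste(config$contexts, collapse = ","))
    chrom_lengths <- config$chrom_lengths
    if (is.null(chrom_lengths)) {
      dna <- Biostrings::readDNAStringSet(config$fasta)
      chrom_lengths <- stats::setNames(Biostrings::width(dna),
                                       sub(" .*", "", names(dna)))
      note("chromosome lengths from FASTA: ",
           paste(names(chrom_lengths), chrom_lengths, collapse = ", "))
    }
    note("stage read: ", config$report_a, " + ", config$report_b)
    sample_a <- read_cytosine_report(config$report_a, config$min_coverage)
    sample_b <- read_cytosine_report(config$report_b, config$min_coverage)
    genes <- read_gene_models(config$gff)
    expr <- read_expression_table(config$expression)

    note("stage profile")
    pair <- pair_samples(sample_a, sample_b, config$min_coverage)
    note("jointly covered sites: ", nrow(pair))
    mc_a <- call_mcs(sample_a, config$min_coverage)
    mc_b <- call_mcs(sample_b, config$min_coverage)
    mc_summary <- rbind(copy(mc_a$summary)[, sample := "A"],
                        copy(mc_b$summary)[, sample := "B"])
    profiles <- rbind(
      copy(bin_profiles(sample_a, chrom_lengths, config$bin_size,
                        config$min_coverage))[, sample := "A"],
      copy(bin_profiles(sample_b, chrom_lengths, config$bin_size,
                        config$min_coverage))[, sample := "B"])
    correlations <- rbind(
      copy(chromosome_correlations(pair, "level"))[, metric := "level"],
      copy(chromosome_correlations(pair, "presence"))[, metric := "presence"])
    divergence <- divergence_summary(pair)
    emit(write_tsv, mc_summary, "mc_summary.tsv", hdr)
    emit(write_tsv, pair, "pair.tsv", hdr)
    emit(write_tsv, profiles, "bin_profiles.tsv", hdr)
    emit(write_tsv, correlations, "correlations.tsv", hdr)
    emit(write_tsv, divergence, "divergence.tsv", hdr)

    note("stage dmr")
    dmr_res <- dmr_stage(pair, chrom_lengths, config)
    for (ctx in config$contexts)
      note("tested windows (", ctx, "): ",
           sum(dmr_res$windows$context == ctx),
           "; window-level DMRs: ",
           sum(dmr_res$dmrs_premerge$context == ctx),
           "; merged DMRs: ", sum(dmr_res$dmrs$context == ctx))
    if (config$write_windows)
      emit(write_tsv, dmr_res$windows, "windows.tsv", hdr)
    emit(write_dmrs_bed, dmr_res$dmrs_premerge, "dmrs_premerge.bed", hdr)
    emit(write_dmrs_bed, dmr_res$dmrs, "dmrs.bed", hdr)
    annotation <- annotate_dmrs(dmr_res$dmrs, genes, config$flank)
    emit(write_tsv, annotation$annotations, "dmr_annotations.tsv", hdr)
    emit(write_tsv, length_distribution(dmr_res$dmrs),
         "dmr_length_distribution.tsv", hdr)

    note("stage associate")
    classes <- classify_expression(expr, config$fdr_alpha, config$min_fpkm)
    association <- foldchange_comparison(classes, annotation,
                                         config$min_abs_fc,
                                         seed = config$seed)
    percentages <- dmr_gene_percentages(classes, annotation)
    emit(write_tsv, classes, "expression_classes.tsv", hdr)
    emit(write_tsv, association$summary, "association_summary.tsv", hdr)
    emit(write_tsv, association$tests, "association_tests.tsv", hdr)
    emit(write_tsv, percentages, "dmr_gene_percentages.tsv", hdr)

    log_path <- file.path(config$outdir, "run.log")
    writeLines(log_lines, log_path)
    created <- c(created, log_path)
    list(pair = pair, mc_a = mc_a, mc_b = mc_b, profiles = profiles,
         correlations = correlations, divergence = divergence,
         windows = dmr_res$windows, dmrs_premerge = dmr_res$dmrs_premerge,
         dmrs = dmr_res$dmrs, annotation = annotation, classes = classes,
         association = association, percentages = percentages,
         paths = created)
  }, error = function(e) {
    unlink(created)
    stop_windmr("pipeline failed: ", conditionMessage(e))
  })
  invisible(res)
}

#' Window testing, DMR calling and merging for one methylome pair
#'
#' The DMR stage of [run_pipeline()], exposed so it can be re-run from a
#' saved pair table (see [read_pair_table()]): tiles the genome, tests the
#' configured contexts, calls window-level DMRs and merges same-trend
#' neighbours.
#'
#' @param pair A `methylome_pair`.
#' @param chrom_lengths Named chromosome lengths.
#' @param config A [pipeline_config()] (only the window/DMR thresholds are
#'   used).
#' @return A list with `windows` (tested windows of all contexts),
#'   `dmrs_premerge`, `dmrs`.
#' @export
dmr_stage <- function(pair, chrom_lengths, config) {
  windows <- tile_windows(chrom_lengths, config$window_size, config$step)
  tested <- rbindlist(lapply(config$contexts, function(ctx)
    test_windows(pair, windows, ctx, config$min_sites)))
  pre_list <- lapply(config$contexts, function(ctx)
    call_dmrs(tested[context == ctx], config$alpha, config$fc_threshold))
  merged <- rbindlist(lapply(pre_list, function(d)
    merge_adjacent(d, pair, config$merge_gap)))
  pre <- rbindlist(pre_list)
  setorder(pre, chrom, start, end)
  setorder(merged, chrom, start, end)
  for (d in list(pre, merged)) {
    setattr(d, "alpha", config$alpha)
    setattr(d, "fc_threshold", config$fc_threshold)
    if (!inherits(d, "dmr_set"))
      setattr(d, "class", c("dmr_set", class(d)))
  }
  setattr(merged, "merged", TRUE)
  setattr(pre, "merged", FALSE)
  list(windows = tested, dmrs_premerge = pre, dmrs = merged)
}

#' Read back a pair table written by [run_pipeline()]
#'
#' @param path Path to `pair.tsv`.
#' @param min_total_reads The coverage threshold it was built with.
#' @return A `methylome_pair`.
#' @export
read_pair_table <- function(path, min_total_reads = 3) {
  dt <- read_tsv(path, colClasses = list(
    character = c("chrom", "strand", "context")))
  setattr(dt, "min_total_reads", min_total_reads)
  setattr(dt, "class", c("methylome_pair", class(dt)))
  dt[]
}
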