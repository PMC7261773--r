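#' Read a Bismark-style per-cytosine report
#'
#' Parses a tab-separated cytosine (CX) report with columns chromosome,
#' 1-based position, strand, methylated read count, unmethylated read count,
#' context (`CG`/`CHG`/`CHH`) and an optional trinucleotide column. Positions
#' are converted to 0-based internally. Sites below the coverage threshold are
#' retained but flagged `covered = FALSE`: whether a site enters the analysis
#' is a joint decision across the two samples, made later by
#' [pair_samples()].
#'
#' @param path Path to the report file.
#' @param min_total_reads Minimum `n_meth + n_unmeth` for a site to be flagged
#'   covered (default 3 reads, applied per sample).
#' @return A `data.table` with columns `chrom`, `pos` (0-based), `strand`,
#'   `n_meth`, `n_unmeth`, `context`, `covered`, sorted by
#'   `(chrom, pos, strand)`. The threshold used is stored in the
#'   `min_total_reads` attribute.
#' @seealso [write_cytosine_report()], [pair_samples()]
#' @export
read_cytosine_report <- function(path, min_total_reads = 3) {
  if (!is.numeric(min_total_reads) || min_total_reads < 0)
    stop_windmr("min_total_reads must be a non-negative number")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines) || all(!nzchar(lines))) {
    dt <- data.table(chrom = character(), pos = integer(),
                     strand = character(), n_meth = integer(),
                     n_unmeth = integer(), context = character(),
                     covered = logical())
    setattr(dt, "min_total_reads", min_total_reads)
    return(dt)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L | nf > 7L)
  if (length(bad))
    stop_windmr("malformed cytosine report line ", bad[1], " in ", path,
                ": expected 6 or 7 tab-separated fields, found ", nf[bad[1]])
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  pos1 <- suppressWarnings(as.integer(m[, 2]))
  n_meth <- suppressWarnings(as.integer(m[, 4]))
  n_unmeth <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(pos1) | is.na(n_meth) | is.na(n_unmeth) |
                 pos1 < 1L | n_meth < 0L | n_unmeth < 0L)
  if (length(bad))
    stop_windmr("malformed cytosine report line ", bad[1], " in ", path,
                ": position and counts must be non-negative integers ",
                "(position 1-based)")
  bad <- which(!m[, 3] %in% c("+", "-"))
  if (length(bad))
    stop_windmr("malformed cytosine report line ", bad[1], " in ", path,
                ": strand must be '+' or '-'")
  bad <- which(!m[, 6] %in% CONTEXTS)
  if (length(bad))
    stop_windmr("unknown context token '", m[bad[1], 6], "' at line ",
                bad[1], " in ", path)
  dt <- data.table(chrom = m[, 1], pos = pos1 - 1L, strand = m[, 3],
                   n_meth = n_meth, n_unmeth = n_unmeth, context = m[, 6])
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand"))) {
    d <- duplicated(dt, by = c("chrom", "pos", "strand"))
    stop_windmr("duplicate site (", dt$chrom[d][1], ", ",
                dt$pos[d][1] + 1L, ", ", dt$strand[d][1], ") in ", path)
  }
  dt[, covered := (n_meth + n_unmeth) >= min_total_reads]
  setorder(dt, chrom, pos, strand)
  setattr(dt, "min_total_reads", min_total_reads)
  dt[]
}

#' Write a per-cytosine report
#'
#' Inverse of [read_cytosine_report()]: emits the 1-based tab-separated
#' dialect, one line per site, sorted by `(chrom, pos, strand)`.
#'
#' @param sites A site table as returned by [read_cytosine_report()] or the
#'   simulator.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cytosine_report <- function(sites, path) {
  dt <- as.data.table(sites)
  req <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context")
  if (!all(req %in% names(dt)))
    stop_windmr("sites must carry columns ", paste(req, collapse = ", "))
  setorder(dt, chrom, pos, strand)
  writeLines(paste(dt$chrom, dt$pos + 1L, dt$strand, dt$n_meth, dt$n_unmeth,
                   dt$context, sep = "\t"), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file and keeps `gene` features only. GFF3 1-based closed
#' intervals are converted to 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.table` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop_windmr("failed to parse GFF3 ", path, ": ",
                               conditionMessage(e)))
  gr <- gr[gr$type == "gene"]
  if (!length(gr))
    return(data.table(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop_windmr("gene feature without an ID attribute in ", path)
  dt <- data.table(gene_id = as.character(ids),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)))
  if (any(!dt$strand %in% c("+", "-")))
    stop_windmr("gene without a defined strand in ", path,
                " (upstream/downstream flanks need one)")
  if (any(dt$end <= dt$start))
    stop_windmr("gene with end <= start in ", path)
  setorder(dt, chrom, start, end)
  dt[]
}

#' Write gene models as GFF3
#'
#' @param genes Gene table as returned by [read_gene_models()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  dt <- as.data.table(genes)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(dt))
    writeLines(paste(dt$chrom, "windmr", "gene", dt$start + 1L, dt$end, ".",
                     dt$strand, ".", paste0("ID=", dt$gene_id), sep = "\t"),
               con)
  invisible(path)
}

#' Read a gene expression table
#'
#' Tab-separated with header `gene_id`, `fpkm_a`, `fpkm_b`, `log2fc`, `fdr`
#' — the output of an upstream differential-expression analysis (sample B
#' over sample A).
#'
#' @param path Path to the table.
#' @return A validated `data.table` of expression records.
#' @export
read_expression_table <- function(path) {
  dt <- read_tsv(path, colClasses = list(character = "gene_id"))
  req <- c("gene_id", "fpkm_a", "fpkm_b", "log2fc", "fdr")
  if (!nrow(dt) && !length(names(dt)))
    return(data.table(gene_id = character(), fpkm_a = numeric(),
                      fpkm_b = numeric(), log2fc = numeric(),
                      fdr = numeric()))
  missing <- setdiff(req, names(dt))
  if (length(missing))
    stop_windmr("expression table ", path, " is missing column(s): ",
                paste(missing, collapse = ", "))
  dt <- dt[, req, with = FALSE]
  if (any(!is.finite(dt$fdr)) || any(dt$fdr < 0 | dt$fdr > 1))
    stop_windmr("expression table ", path, ": fdr values must lie in [0, 1]")
  if (any(dt$fpkm_a < 0 | dt$fpkm_b < 0, na.rm = TRUE))
    stop_windmr("expression table ", path, ": FPKM values must be >= 0")
  dt[]
}

#' Write a gene expression table
#'
#' @param records Expression table (see [read_expression_table()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_table <- function(records, path) {
  dt <- as.data.table(records)
  write_tsv(dt[, .(gene_id, fpkm_a, fpkm_b, log2fc, fdr)], path)
}

#' Write called DMRs as BED6+2
#'
#' Coordinates are 0-based half-open. Column 4 is `context:trend`, column 5
#' the Phred-like score `-10*log10(q)` rounded and capped at 1000, column 6
#' `.` (regions are unstranded), followed by `fold_change` and `q_value`.
#'
#' @param dmrs A DMR table (see [call_dmrs()]).
#' @param path Output path.
#' @param header_lines Optional extra comment lines (provenance).
#' @return The path, invisibly.
#' @export
write_dmrs_bed <- function(dmrs, path, header_lines = character()) {
  dt <- as.data.table(dmrs)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(paste0("# ", header_lines),
               "# chrom\tstart\tend\tname\tscore\tstrand\tfold_change\tq_value"),
             con)
  if (nrow(dt)) {
    score <- ifelse(dt$q_value <= 0, 1000,
                    pmin(1000, round(-10 * log10(dt$q_value))))
    writeLines(paste(dt$chrom, dt$start, dt$end,
                     paste0(dt$context, ":", dt$trend), score, ".",
                     fmt_num(dt$fold_change), fmt_num(dt$q_value),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a DMR BED file written by [write_dmrs_bed()]
#'
#' @param path Path to the BED file.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `context`,
#'   `trend`, `fold_change`, `q_value`.
#' @export
read_dmrs_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      trend = character(), fold_change = numeric(),
                      q_value = numeric()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 8L))
    stop_windmr("malformed DMR BED line in ", path)
  m <- matrix(unlist(f), ncol = 8, byrow = TRUE)
  nm <- strsplit(m[, 4], ":", fixed = TRUE)
  data.table(chrom = m[, 1], start = as.integer(m[, 2]),
             end = as.integer(m[, 3]),
             context = vapply(nm, `[`, "", 1),
             trend = vapply(nm, `[`, "", 2),
             fold_change = as.numeric(m[, 7]),
             q_value = as.numeric(m[, 8]))
}
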