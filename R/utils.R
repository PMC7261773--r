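# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_windmr <- function(...) stop(..., call. = FALSE)

# numeric formatting that survives a write -> read round trip bit-identically
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.infinite(v)) return(if (v > 0) "Inf" else "-Inf")
    sprintf("%.17g", v)
  }, character(1))
  out
}

# run an expression with a temporary RNG state derived from `seed`,
# restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits; used for
# provenance headers (configuration fingerprinting, not cryptography)
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h a double so values
    # above 2^31 never hit R's 32-bit integer limit
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    # 32-bit modular multiply by the FNV prime 16777619, split to stay in
    # double precision: prime = 2^24 + 403
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  # render as hex in two 16-bit halves (the value exceeds integer range)
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

config_hash <- function(config) {
  fnv1a32(paste(deparse(config, control = "all"), collapse = ""))
}

check_chrom_lengths <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop_windmr("chrom_lengths must be a named vector of chromosome lengths")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop_windmr("chromosome lengths must be positive finite numbers")
  if (anyDuplicated(names(chrom_lengths)))
    stop_windmr("duplicated chromosome names in chrom_lengths")
  chrom_lengths
}

# write a data.table as TSV with '#'-prefixed header lines; numeric columns
# rendered with fmt_num so round trips are exact
write_tsv <- function(dt, path, header_lines = character()) {
  dt <- as.data.table(dt)
  out <- copy(dt)
  for (col in names(out)) {
    if (is.double(out[[col]])) set(out, j = col, value = fmt_num(out[[col]]))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

read_tsv <- function(path, colClasses = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(data.table())
  fread(text = body, sep = "\t", header = TRUE, colClasses = colClasses,
        na.strings = "NA")
}
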