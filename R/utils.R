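# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read all lines of a text file, transparently decompressing gzip
#'
#' @param path File path; plain text or gzip-compressed.
#' @return Character vector of lines.
#' @keywords internal
read_text_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Write lines with "\n" separators in binary mode so output bytes are
# platform-independent (determinism is part of the output contract).
write_text_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  }
  invisible(path)
}

# Locale-independent (C collation) ordering of genomic sites.
site_order <- function(chrom, pos) {
  order(chrom, pos, method = "radix")
}

sites_sorted <- function(chrom, pos) {
  identical(site_order(chrom, pos), seq_along(chrom))
}

# Compact numeric formatting used for betas / percentages in text outputs.
# Deterministic for a given value, so re-writing identical records is
# byte-stable.
fmt_num <- function(x) {
  sprintf("%g", x)
}

# Coerce a character vector to integer, stopping with the offending 1-based
# line number on failure. Used by the text-format parsers.
parse_int_field <- function(x, line_no, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) | out != floor(out))
  if (length(bad)) {
    stop(sprintf("line %d: invalid %s field '%s'", line_no[bad[1]], what, x[bad[1]]),
         call. = FALSE)
  }
  as.integer(out)
}
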