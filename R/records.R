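#' Construct a table of per-CpG count records
#'
#' The package's primitive site-level representation: one row per CpG with
#' methylated and unmethylated read counts. Coordinates are 0-based
#' (the position of the cytosine); Bismark's 1-based coverage dialect is
#' converted at the I/O boundary.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based cytosine positions.
#' @param count_meth,count_unmeth Nonnegative integer read counts.
#' @return A `data.frame` with columns `chrom`, `pos`, `count_meth`,
#'   `count_unmeth`.
#' @examples
#' cpg_records("chr1", 99L, 3L, 1L)
#' @export
cpg_records <- function(chrom = character(), pos = integer(),
                        count_meth = integer(), count_unmeth = integer()) {
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    count_meth = as.integer(count_meth),
    count_unmeth = as.integer(count_unmeth),
    stringsAsFactors = FALSE
  )
  validate_cpg_records(df)
  df
}

validate_cpg_records <- function(records) {
  needed <- c("chrom", "pos", "count_meth", "count_unmeth")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("records must be a data.frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(records)) {
    if (any(records$count_meth < 0) || any(records$count_unmeth < 0)) {
      stop("negative counts are not allowed", call. = FALSE)
    }
    if (any(records$pos < 0)) {
      stop("positions must be nonnegative 0-based coordinates", call. = FALSE)
    }
    if (any(!nzchar(records$chrom))) {
      stop("chrom must be nonempty", call. = FALSE)
    }
  }
  invisible(records)
}

#' Total coverage and methylation level (beta) of count records
#'
#' `site_coverage()` returns methylated + unmethylated counts;
#' `site_beta()` returns the per-site methylation estimate
#' `count_meth / coverage`, `NA` where coverage is zero.
#'
#' @param records A CpG record table (see [cpg_records()]).
#' @return Numeric vector, one value per record.
#' @export
site_coverage <- function(records) {
  records$count_meth + records$count_unmeth
}

#' @rdname site_coverage
#' @export
site_beta <- function(records) {
  cov <- site_coverage(records)
  ifelse(cov > 0, records$count_meth / cov, NA_real_)
}

# Alphabet of the Bismark-style methylation-call string:
#   Z/z CpG, X/x CHG, H/h CHH, U/u unknown context, '.' non-cytosine.
# Uppercase = unconverted (methylated), lowercase = converted (unmethylated).
CALL_ALPHABET_RE <- "^[ZzXxHhUu.]*$"

#' Construct a table of methylation-call reads
#'
#' One row per primary alignment, carrying the aligner's per-base
#' methylation-call string (`Z`/`z` CpG, `X`/`x` CHG, `H`/`h` CHH, `U`/`u`
#' unknown, `.` non-cytosine; uppercase means unconverted i.e. methylated).
#'
#' @param read_id Character read names.
#' @param mate One of `"R1"`, `"R2"`, `"unpaired"` per read.
#' @param calls Methylation-call strings (empty for unmapped reads).
#' @param mapped Logical; whether the read aligned.
#' @return A `data.frame` with those four columns.
#' @export
methylation_call_reads <- function(read_id = character(), mate = character(),
                                   calls = character(), mapped = logical()) {
  df <- data.frame(
    read_id = as.character(read_id),
    mate = as.character(mate),
    calls = as.character(calls),
    mapped = as.logical(mapped),
    stringsAsFactors = FALSE
  )
  validate_call_reads(df)
  df
}

validate_call_reads <- function(reads) {
  needed <- c("read_id", "mate", "calls", "mapped")
  if (!is.data.frame(reads) || !all(needed %in% names(reads))) {
    stop("reads must be a data.frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(reads)) {
    bad_mate <- setdiff(unique(reads$mate), c("R1", "R2", "unpaired"))
    if (length(bad_mate)) {
      stop("invalid mate value(s): ", paste(bad_mate, collapse = ", "),
           call. = FALSE)
    }
    bad <- which(!grepl(CALL_ALPHABET_RE, reads$calls))
    if (length(bad)) {
      stop("invalid character in methylation-call string of read '",
           reads$read_id[bad[1]], "'", call. = FALSE)
    }
  }
  invisible(reads)
}

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based, half-open (`[start, end)`), the BED convention,
#' used for feature-level coverage (promoters, CpG islands, ...).
#'
#' @param chrom Character chromosome names.
#' @param start,end Integer bounds, `0 <= start < end`.
#' @param name Optional feature names (`NA` allowed).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), name = NA_character_) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = rep_len(as.character(name), length(chrom)),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(!nzchar(df$chrom))) stop("chrom must be nonempty", call. = FALSE)
    if (any(df$start < 0)) stop("start must be >= 0", call. = FALSE)
    if (any(df$start >= df$end)) {
      i <- which(df$start >= df$end)[1]
      stop(sprintf("interval %s:%d-%d has start >= end",
                   df$chrom[i], df$start[i], df$end[i]), call. = FALSE)
    }
  }
  df
}
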