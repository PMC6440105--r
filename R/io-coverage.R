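#' Read a Bismark-dialect per-CpG coverage file
#'
#' The coverage dialect has six tab-separated columns: chromosome, 1-based
#' start, end (equal to start for a single cytosine), methylation percentage,
#' methylated count, unmethylated count. Positions are converted to 0-based
#' coordinates on read. The printed percentage is cross-checked against
#' `100 * count_meth / coverage`; when they disagree by more than
#' `percent_tol` percentage points a warning is raised and the counts win
#' (printed percentages are rounded, counts are the primitive).
#'
#' @param path Coverage file (plain or gzip-compressed).
#' @param merge_strands If `TRUE`, a record at position `p + 1` whose
#'   chromosome also carries a record at `p` is treated as the reverse-strand
#'   half of the CpG dyad and its counts are summed onto the forward-strand
#'   cytosine at `p`. Off by default; both strand-merged and strand-split
#'   coverage files exist in the wild.
#' @param percent_tol Disagreement tolerance, percentage points.
#' @return A CpG record table (see [cpg_records()]), in file order.
#' @examples
#' f <- tempfile(fileext = ".cov")
#' writeLines("chr1\t100\t100\t75\t3\t1", f)
#' read_bismark_coverage(f)
#' @export
read_bismark_coverage <- function(path, merge_strands = FALSE,
                                  percent_tol = 0.5) {
  lines <- read_text_lines(path)
  keep <- nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(cpg_records())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    i <- which(nf != 6L)[1]
    stop(sprintf("line %d: expected 6 tab-separated fields, found %d",
                 line_no[i], nf[i]), call. = FALSE)
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 6L, byrow = TRUE)
  start <- parse_int_field(m[, 2], line_no, "start")
  count_meth <- parse_int_field(m[, 5], line_no, "methylated count")
  count_unmeth <- parse_int_field(m[, 6], line_no, "unmethylated count")
  neg <- which(count_meth < 0 | count_unmeth < 0)
  if (length(neg)) {
    stop(sprintf("line %d: negative count", line_no[neg[1]]), call. = FALSE)
  }
  pct_stated <- suppressWarnings(as.numeric(m[, 4]))
  cov <- count_meth + count_unmeth
  has_cov <- cov > 0 & !is.na(pct_stated)
  pct_comp <- ifelse(cov > 0, 100 * count_meth / cov, NA_real_)
  off <- has_cov & abs(pct_stated - pct_comp) > percent_tol
  if (any(off)) {
    warning(sprintf(
      "%d record(s) where the stated methylation percentage disagrees with the counts by > %g points (first at line %d); counts used",
      sum(off), percent_tol, line_no[which(off)[1]]), call. = FALSE)
  }
  records <- cpg_records(
    chrom = m[, 1], pos = start - 1L,
    count_meth = count_meth, count_unmeth = count_unmeth
  )
  if (merge_strands) records <- merge_cpg_strands(records)
  records
}

#' Merge strand-split CpG records onto the forward-strand cytosine
#'
#' In strand-split coverage files the reverse-strand cytosine of a CpG dyad
#' is reported one base downstream of the forward one. Records at position
#' `p + 1` that have a companion at `p` on the same chromosome get their
#' counts added to the `p` record and are dropped.
#'
#' @param records CpG record table.
#' @return Merged record table, original order of retained records.
#' @export
merge_cpg_strands <- function(records) {
  validate_cpg_records(records)
  if (!nrow(records)) return(records)
  key <- paste(records$chrom, records$pos)
  fwd_of <- match(paste(records$chrom, records$pos - 1L), key)
  is_rev <- !is.na(fwd_of)
  if (!any(is_rev)) return(records)
  tgt <- fwd_of[is_rev]
  records$count_meth[tgt] <- records$count_meth[tgt] +
    records$count_meth[is_rev]
  records$count_unmeth[tgt] <- records$count_unmeth[tgt] +
    records$count_unmeth[is_rev]
  out <- records[!is_rev, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write CpG records as a Bismark-dialect coverage file
#'
#' Emits the 1-based six-column dialect read by [read_bismark_coverage()];
#' the percentage column is recomputed from the counts (0 when coverage is
#' zero), so write -> read -> write is byte-stable.
#'
#' @param records CpG record table, sorted by (chrom, pos).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bismark_coverage <- function(records, path) {
  validate_cpg_records(records)
  if (!sites_sorted(records$chrom, records$pos)) {
    stop("records must be sorted by (chrom, pos)", call. = FALSE)
  }
  if (!nrow(records)) {
    return(write_text_lines(character(), path))
  }
  cov <- site_coverage(records)
  pct <- ifelse(cov > 0, 100 * records$count_meth / cov, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   records$chrom, records$pos + 1L, records$pos + 1L,
                   fmt_num(pct), records$count_meth, records$count_unmeth)
  write_text_lines(lines, path)
}

#' Write a bedGraph methylation track
#'
#' One 0-based half-open single-base interval per covered site with the
#' methylation level (beta) as the score; zero-coverage sites are omitted.
#' bedGraph is emitted rather than binary bigwig so track output is
#' bit-exactly testable; standard converters turn it into bigwig.
#'
#' @param records CpG record table, sorted by (chrom, pos).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(records, path) {
  validate_cpg_records(records)
  if (!sites_sorted(records$chrom, records$pos)) {
    stop("records must be sorted by (chrom, pos)", call. = FALSE)
  }
  cov <- site_coverage(records)
  keep <- cov > 0
  lines <- sprintf("%s\t%d\t%d\t%s",
                   records$chrom[keep], records$pos[keep],
                   records$pos[keep] + 1L,
                   fmt_num(records$count_meth[keep] / cov[keep]))
  write_text_lines(lines, path)
}

#' Read genomic feature intervals from a BED file
#'
#' Accepts BED3 and wider; the fourth column, when present, is kept as the
#' feature name. `track`, `browser` and `#` comment lines are skipped.
#' Coordinates stay in BED's native 0-based half-open convention.
#'
#' @param path BED file (plain or gzip-compressed).
#' @return An interval table (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  lines <- read_text_lines(path)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(genomic_intervals())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1]
    stop(sprintf("line %d: BED needs >= 3 columns, found %d",
                 line_no[i], nf[i]), call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- parse_int_field(vapply(parts, `[[`, "", 2L), line_no, "start")
  end <- parse_int_field(vapply(parts, `[[`, "", 3L), line_no, "end")
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("line %d: start >= end", line_no[bad[1]]), call. = FALSE)
  }
  name <- ifelse(nf >= 4L,
                 vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else NA_character_, ""),
                 NA_character_)
  genomic_intervals(chrom, start, end, name)
}
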