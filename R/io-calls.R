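#' Read methylation-call reads from a SAM/BAM file
#'
#' Extracts the per-base methylation-call string (the Bismark `XM` tag
#' dialect) from every primary alignment record. Secondary and supplementary
#' alignments are skipped. Unmapped reads are returned with `mapped = FALSE`
#' and an empty call string. Mapped primary records lacking the call tag are
#' counted, reported with a warning, and skipped.
#'
#' @param path SAM (`.sam`) or BAM file. SAM input is converted on the fly.
#' @param tag Name of the methylation-call tag (default `"XM"`).
#' @param include_position Also return `chrom` and 1-based alignment `pos`
#'   columns for mapped reads (used to tally calls back onto sites).
#' @return A call-read table (see [methylation_call_reads()]); the number of
#'   skipped tag-less records is attached as attribute `n_missing_tag`.
#' @export
read_methylation_calls <- function(path, tag = "XM", include_position = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  what <- c("qname", "flag")
  if (include_position) what <- c(what, "rname", "pos")
  param <- Rsamtools::ScanBamParam(
    what = what, tag = tag,
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  flag <- res$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  paired <- bitwAnd(flag, 1L) > 0L
  first <- bitwAnd(flag, 64L) > 0L
  mate <- ifelse(!paired, "unpaired", ifelse(first, "R1", "R2"))
  calls <- res$tag[[tag]]
  if (is.null(calls)) calls <- rep(NA_character_, length(flag))
  missing_tag <- mapped & is.na(calls)
  n_missing <- sum(missing_tag)
  if (n_missing > 0) {
    warning(sprintf(
      "%d mapped primary record(s) lack the %s methylation-call tag; skipped",
      n_missing, tag), call. = FALSE)
  }
  calls[!mapped] <- ""
  keep <- !missing_tag
  reads <- methylation_call_reads(
    read_id = res$qname[keep], mate = mate[keep],
    calls = calls[keep], mapped = mapped[keep]
  )
  if (include_position) {
    reads$chrom <- as.character(res$rname)[keep]
    reads$pos <- res$pos[keep]
  }
  attr(reads, "n_missing_tag") <- n_missing
  reads
}

#' Write methylation-call reads as a SAM file
#'
#' The writing counterpart of [read_methylation_calls()], used by the
#' simulator. Mapped reads need `chrom` and `site_pos`/`call_col` (or `pos`)
#' columns so the call string is anchored to genomic coordinates; unmapped
#' reads are written with the unmapped flag and no call tag.
#'
#' @param reads Call-read table. For mapped reads, either a `pos` column
#'   (1-based leftmost alignment position) or `site_pos` + `call_col`
#'   (0-based site coordinate and 1-based column of the CpG call within the
#'   read) must be present alongside `chrom`.
#' @param path Output SAM path.
#' @param chrom_lengths Named integer vector of reference lengths; inferred
#'   generously from the data when omitted.
#' @param tag Methylation-call tag name.
#' @return `path`, invisibly.
#' @export
write_methylation_calls <- function(reads, path, chrom_lengths = NULL,
                                    tag = "XM") {
  validate_call_reads(reads)
  mapped <- reads$mapped
  if (any(mapped) && is.null(reads$chrom)) {
    stop("mapped reads need a 'chrom' column to be written as SAM",
         call. = FALSE)
  }
  pos1 <- rep(0L, nrow(reads))
  if (any(mapped)) {
    if (!is.null(reads$pos)) {
      pos1[mapped] <- reads$pos[mapped]
    } else if (!is.null(reads$site_pos) && !is.null(reads$call_col)) {
      pos1[mapped] <- reads$site_pos[mapped] + 1L - (reads$call_col[mapped] - 1L)
    } else {
      stop("mapped reads need 'pos' or 'site_pos' + 'call_col' columns",
           call. = FALSE)
    }
    if (any(pos1[mapped] < 1L)) {
      stop("alignment positions must be >= 1", call. = FALSE)
    }
  }
  chroms <- if (any(mapped)) sort(unique(reads$chrom[mapped])) else character()
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) {
      i <- mapped & reads$chrom == ch
      max(pos1[i] + nchar(reads$calls[i])) + 10L
    }, integer(1))
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths))
  )
  flag <- integer(nrow(reads))
  flag[reads$mate == "R1"] <- 1L + 64L
  flag[reads$mate == "R2"] <- 1L + 128L
  flag[!mapped] <- flag[!mapped] + 4L
  len <- nchar(reads$calls)
  chrom_col <- reads$chrom %||% rep("*", nrow(reads))
  body <- ifelse(
    mapped,
    sprintf("%s\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t*\t%s:Z:%s",
            reads$read_id, flag, chrom_col,
            pos1, len, strrep("N", len), tag, reads$calls),
    sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t*\t*", reads$read_id, flag)
  )
  write_text_lines(c(header, body), path)
}
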