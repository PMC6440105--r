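# Independent oracles and small fixture builders shared across tests.

# Quadratic brute-force feature coverage: all-pairs overlap test, no sweep,
# no binary search. The reference implementation feature_coverage() is
# checked against this on random instances.
brute_feature_coverage <- function(records, features) {
  if (!nrow(features)) return(NA_real_)
  covered <- records[site_coverage(records) > 0, , drop = FALSE]
  hit <- vapply(seq_len(nrow(features)), function(i) {
    any(covered$chrom == features$chrom[i] &
          covered$pos >= features$start[i] &
          covered$pos < features$end[i])
  }, logical(1))
  mean(hit)
}

# Quadratic brute-force CpG density: for each covered site count all
# reference positions within the window by direct comparison.
brute_cpg_density <- function(records, reference_cpgs, window) {
  covered <- records[site_coverage(records) > 0, , drop = FALSE]
  out <- integer(0)
  for (ch in unique(covered$chrom)) {
    ref <- reference_cpgs[[ch]]
    if (is.null(ref)) next
    p <- covered$pos[covered$chrom == ch]
    out <- c(out, vapply(p, function(x) {
      sum(ref >= x - window & ref <= x + window)
    }, integer(1)))
  }
  out
}

# Random record / feature instance generator for oracle-equivalence tests.
random_instance <- function(n_sites, n_features, genome = 50000L,
                            chroms = c("chr1", "chr2")) {
  records <- cpg_records(
    chrom = sample(chroms, n_sites, replace = TRUE),
    pos = sample.int(genome, n_sites, replace = TRUE) - 1L,
    count_meth = stats::rpois(n_sites, 2),
    count_unmeth = stats::rpois(n_sites, 2)
  )
  start <- sample.int(genome - 200L, n_features, replace = TRUE) - 1L
  genomic_intervals(
    chrom = sample(chroms, n_features, replace = TRUE),
    start = start,
    end = start + sample.int(200L, n_features, replace = TRUE)
  ) -> features
  list(records = records, features = features)
}

# Tally per-site counts from a SAM file read back through the public
# reader, locating the CpG call inside each call string. Independent of
# tally_call_reads() internals.
tally_from_sam <- function(path) {
  reads <- read_methylation_calls(path, include_position = TRUE)
  r <- reads[reads$mapped, , drop = FALSE]
  hit <- regexpr("[Zz]", r$calls)
  stopifnot(all(hit > 0))
  site_pos <- r$pos - 1L + (hit - 1L)
  meth <- substr(r$calls, hit, hit) == "Z"
  key <- paste0(r$chrom, ":", site_pos)
  cm <- tapply(meth, key, sum)
  tot <- tapply(rep(1L, nrow(r)), key, sum)
  keys <- names(cm)
  chrom <- sub(":[0-9]+$", "", keys)
  pos <- as.integer(sub("^.*:", "", keys))
  o <- order(chrom, pos, method = "radix")
  cpg_records(chrom[o], pos[o], as.integer(cm[o]), as.integer(tot - cm)[o])
}

# Drop zero-coverage sites and sort: the view of the records that call-read
# tallies can see.
covered_sorted <- function(records) {
  r <- records[site_coverage(records) > 0, , drop = FALSE]
  o <- order(r$chrom, r$pos, method = "radix")
  r <- r[o, , drop = FALSE]
  rownames(r) <- NULL
  r
}

# Strip comment lines so text reports can be compared outside the
# timestamped region.
non_comment_lines <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "#")]
}
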