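#' Mapped / unmapped read counts
#'
#' Partitions primary reads by their mapped flag: the most basic library
#' quality indicator.
#'
#' @param reads Call-read table (see [methylation_call_reads()]).
#' @return Named list with integer `mapped` and `unmapped`.
#' @export
read_metrics <- function(reads) {
  validate_call_reads(reads)
  list(mapped = sum(reads$mapped), unmapped = sum(!reads$mapped))
}

#' Number of CpGs observed at a minimum coverage threshold
#'
#' @param records CpG record table.
#' @param min_cov Minimum total coverage, `>= 1`. May be a vector, in which
#'   case a named integer vector is returned.
#' @return Integer count(s) of sites with coverage `>= min_cov`.
#' @export
cpg_coverage_count <- function(records, min_cov = 1L) {
  validate_cpg_records(records)
  if (any(min_cov < 1)) stop("min_cov must be >= 1", call. = FALSE)
  cov <- site_coverage(records)
  out <- vapply(as.integer(min_cov), function(k) sum(cov >= k), integer(1))
  names(out) <- as.character(as.integer(min_cov))
  if (length(out) == 1L) unname(out) else out
}

#' M-bias profile: methylation level by position within the read
#'
#' Tallies CpG calls (`Z` methylated, `z` unmethylated) at each read
#' position, separately per mate; all other call characters are ignored.
#' A flat profile is expected from a well-constructed library — deviation
#' from uniformity at read ends typically indicates library construction or
#' trimming artifacts.
#'
#' @param reads Call-read table; only mapped reads contribute.
#' @return Object of class `mbias_profile`: a named list (per mate present)
#'   of data frames with `position` (0-based), `count_meth`, `count_unmeth`
#'   and `fraction` (`NA` where no CpG call was seen).
#' @export
mbias_profile <- function(reads) {
  validate_call_reads(reads)
  r <- reads[reads$mapped & nzchar(reads$calls), , drop = FALSE]
  out <- list()
  for (m in intersect(c("R1", "R2", "unpaired"), unique(r$mate))) {
    calls <- r$calls[r$mate == m]
    n <- nchar(calls)
    ch <- unlist(strsplit(calls, "", fixed = TRUE), use.names = FALSE)
    pos <- sequence(n)
    L <- max(n)
    cm <- tabulate(pos[ch == "Z"], nbins = L)
    cu <- tabulate(pos[ch == "z"], nbins = L)
    tot <- cm + cu
    out[[m]] <- data.frame(
      position = seq_len(L) - 1L,
      count_meth = cm, count_unmeth = cu,
      fraction = ifelse(tot > 0, cm / tot, NA_real_)
    )
  }
  structure(out, class = "mbias_profile")
}

#' Downsampling saturation curve of CpG coverage
#'
#' Estimates how many CpGs would remain covered at reduced sequencing depth
#' by binomially thinning each site's coverage: at fraction `f` every read is
#' kept independently with probability `f`. Thinning is nested — reads
#' retained at a smaller fraction are a subset of those retained at a larger
#' one — so each realization of the curve is nondecreasing in `f` by
#' construction, and `f = 1` reproduces the exact covered-site count. A curve
#' still rising at `f = 1` indicates deeper sequencing would reveal more
#' CpGs. Coverage files carry no read identity, so thinning operates on
#' per-site counts rather than on raw reads.
#'
#' @param records CpG record table.
#' @param fractions Strictly increasing retention fractions in `(0, 1]`.
#' @param min_cov Coverage threshold for "covered".
#' @param seed Integer seed; the curve is bit-reproducible given
#'   (input, seed).
#' @return Object of class `saturation_curve`: data frame with `fraction`
#'   and `covered_cpgs`.
#' @export
saturation_curve <- function(records,
                             fractions = c(0.01, 0.05, 0.1, 0.2, 0.4, 0.6,
                                           0.8, 1),
                             min_cov = 1L, seed = 17L) {
  validate_cpg_records(records)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("fractions must be strictly increasing", call. = FALSE)
  }
  cov <- site_coverage(records)
  K <- length(fractions)
  thinned <- matrix(0L, nrow = length(cov), ncol = K)
  withr::with_seed(as.integer(seed), {
    cur <- as.integer(cov)
    cur_f <- 1
    for (k in rev(seq_len(K))) {
      f <- fractions[k]
      if (f < cur_f) {
        cur <- stats::rbinom(length(cur), cur, f / cur_f)
        cur_f <- f
      }
      thinned[, k] <- cur
    }
  })
  structure(
    data.frame(fraction = fractions,
               covered_cpgs = colSums(thinned >= min_cov)),
    class = c("saturation_curve", "data.frame")
  )
}

#' Fraction of CpGs with non-binary methylation status
#'
#' In single cells each covered allele is essentially fully methylated or
#' fully unmethylated, so intermediate per-site methylation values suggest
#' technical noise. Among sites with coverage `>= min_cov`, returns the
#' fraction whose beta lies strictly between `low` and `high`.
#'
#' @param records CpG record table.
#' @param min_cov Coverage threshold (intermediate values at low coverage are
#'   expected from sampling alone).
#' @param low,high Open-interval bounds, `0 <= low < high <= 1`.
#' @return Fraction in `[0, 1]`, or `NA` when no site reaches `min_cov`.
#' @export
discretization_fraction <- function(records, min_cov = 5L, low = 0.1,
                                    high = 0.9) {
  validate_cpg_records(records)
  if (!(low >= 0 && low < high && high <= 1)) {
    stop("need 0 <= low < high <= 1", call. = FALSE)
  }
  cov <- site_coverage(records)
  beta <- site_beta(records)[cov >= min_cov]
  if (!length(beta)) return(NA_real_)
  mean(beta > low & beta < high)
}

#' Fraction of genomic features covered by at least one CpG
#'
#' For each interval (promoter, CpG island, ...), checks whether it contains
#' at least one site with coverage >= 1, via binary search over the sorted
#' site positions per chromosome. Intervals are half-open: a site at
#' `end` is outside.
#'
#' @param records CpG record table.
#' @param features Interval table (see [genomic_intervals()]).
#' @return Fraction of covered features, or `NA` for an empty feature set.
#' @export
feature_coverage <- function(records, features) {
  validate_cpg_records(records)
  if (!nrow(features)) return(NA_real_)
  covered <- records[site_coverage(records) > 0, , drop = FALSE]
  pos_by_chrom <- lapply(split(covered$pos, covered$chrom), sort)
  hit <- logical(nrow(features))
  for (ch in unique(features$chrom)) {
    p <- pos_by_chrom[[ch]]
    idx <- which(features$chrom == ch)
    if (is.null(p)) next
    n_in <- findInterval(features$end[idx] - 1L, p) -
      findInterval(features$start[idx] - 1L, p)
    hit[idx] <- n_in > 0L
  }
  mean(hit)
}

#' Bisulfite conversion rate from non-CpG cytosine calls
#'
#' Non-CpG cytosines are essentially unmethylated in most mammalian tissues,
#' so the fraction of CHH/CHG calls read as converted (lowercase `h`/`x`)
#' estimates the chemical conversion efficiency and should be close to 1.
#' CHH and CHG contexts are pooled.
#'
#' @param reads Call-read table; only mapped reads contribute.
#' @return Rate in `[0, 1]`, or `NA` when no non-CpG cytosine call is
#'   present.
#' @export
bisulfite_conversion_rate <- function(reads) {
  validate_call_reads(reads)
  calls <- reads$calls[reads$mapped]
  cnt <- vapply(c("h", "x", "H", "X"), function(chr) {
    sum(nchar(calls)) - sum(nchar(gsub(chr, "", calls, fixed = TRUE)))
  }, numeric(1))
  denom <- sum(cnt)
  if (denom == 0) return(NA_real_)
  unname((cnt["h"] + cnt["x"]) / denom)
}

#' Histogram of per-site methylation values
#'
#' Bins the betas of sites with coverage `>= min_cov` into `n_bins`
#' equal-width bins on `[0, 1]`; bins are left-closed and the last bin is
#' right-closed, so counts sum to the number of qualifying sites.
#'
#' @param records CpG record table.
#' @param min_cov Coverage threshold.
#' @param n_bins Number of bins, `>= 1`.
#' @return Data frame with `lower`, `upper`, `count`.
#' @export
methylation_distribution <- function(records, min_cov = 1L, n_bins = 20L) {
  validate_cpg_records(records)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  cov <- site_coverage(records)
  beta <- site_beta(records)[cov >= min_cov]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(beta, breaks, rightmost.closed = TRUE)
  data.frame(
    lower = breaks[-(n_bins + 1L)],
    upper = breaks[-1L],
    count = tabulate(bin, nbins = n_bins)
  )
}

#' CpG density around observed sites
#'
#' For every covered site, counts the reference CpGs within `window` bases
#' on either side (inclusive, and including the site itself, so an isolated
#' reference CpG has density 1). Similar density distributions across
#' samples indicate coverage of similar genomic regions. Counting uses
#' binary search over the sorted reference positions.
#'
#' @param records CpG record table.
#' @param reference_cpgs Named list, chromosome -> sorted integer vector of
#'   0-based reference CpG positions.
#' @param window Half-window in bases.
#' @return List with `density` (per covered site, in record order),
#'   `histogram` (data frame `density`, `count`) and `n_skipped` (covered
#'   sites on chromosomes absent from the reference).
#' @export
cpg_density_distribution <- function(records, reference_cpgs, window = 100L) {
  validate_cpg_records(records)
  covered <- records[site_coverage(records) > 0, , drop = FALSE]
  dens <- integer(0)
  n_skipped <- 0L
  for (ch in unique(covered$chrom)) {
    p <- covered$pos[covered$chrom == ch]
    ref <- reference_cpgs[[ch]]
    if (is.null(ref)) {
      n_skipped <- n_skipped + length(p)
      next
    }
    if (is.unsorted(ref)) stop("reference positions must be sorted",
                               call. = FALSE)
    d <- findInterval(p + window, ref) - findInterval(p - window - 1L, ref)
    dens <- c(dens, d)
  }
  tab <- table(dens)
  list(
    density = dens,
    histogram = data.frame(density = as.integer(names(tab)),
                           count = as.integer(tab)),
    n_skipped = n_skipped
  )
}

#' Uniform random subsample of CpG sites
#'
#' Metric estimation cost scales with the number of sites; a uniform
#' subsample of the ~28 million human CpGs as small as one million sites
#' yields unbiased and stable QC estimates, so metrics can optionally be
#' computed on a subsample. Sampling is without replacement, order
#' preserving, and bit-reproducible given the seed.
#'
#' @param records CpG record table.
#' @param n Number of sites to keep (`min(n, nrow(records))` retained).
#' @param seed Integer seed.
#' @return Subsampled record table in original order.
#' @export
subsample_sites <- function(records, n, seed = 17L) {
  validate_cpg_records(records)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (n >= nrow(records)) return(records)
  idx <- withr::with_seed(as.integer(seed),
                          sort(sample.int(nrow(records), n)))
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
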