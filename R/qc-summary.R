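#' QC configuration with documented defaults
#'
#' Central knob set for [compute_qc_summary()]. All values are echoed into
#' the summary so every report records the parameters it was computed under.
#'
#' @param min_cov_thresholds Coverage thresholds for the covered-CpG counts.
#' @param disc_min_cov,disc_low,disc_high Coverage threshold and open-interval
#'   bounds for the discretization (non-binary methylation) fraction.
#' @param saturation_fractions,saturation_min_cov Retention grid and coverage
#'   threshold for the saturation curve.
#' @param hist_min_cov,n_bins Threshold and bin count for the methylation
#'   value histogram.
#' @param density_window Half-window (bp) for CpG density.
#' @param subsample Logical; compute site-level metrics on a subsample.
#' @param subsample_n Subsample size when enabled. One million sites is
#'   enough for stable, unbiased estimates genome-wide.
#' @param seed Seed for all stochastic metrics (subsampling, saturation);
#'   recorded in the summary.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_cov_thresholds = c(1L, 5L, 10L),
                      disc_min_cov = 5L, disc_low = 0.1, disc_high = 0.9,
                      saturation_fractions = c(0.01, 0.05, 0.1, 0.2, 0.4,
                                               0.6, 0.8, 1),
                      saturation_min_cov = 1L,
                      hist_min_cov = 1L, n_bins = 20L,
                      density_window = 100L,
                      subsample = FALSE, subsample_n = 1e6,
                      seed = 17L) {
  stopifnot(all(min_cov_thresholds >= 1), subsample_n >= 1)
  structure(list(
    min_cov_thresholds = as.integer(min_cov_thresholds),
    disc_min_cov = as.integer(disc_min_cov),
    disc_low = disc_low, disc_high = disc_high,
    saturation_fractions = saturation_fractions,
    saturation_min_cov = as.integer(saturation_min_cov),
    hist_min_cov = as.integer(hist_min_cov), n_bins = as.integer(n_bins),
    density_window = as.integer(density_window),
    subsample = isTRUE(subsample), subsample_n = as.integer(subsample_n),
    seed = as.integer(seed)
  ), class = "qc_config")
}

#' Compute the full per-sample QC summary
#'
#' Runs every metric of the QC panel for one sample: read mapping counts,
#' covered CpGs at each threshold, mean methylation, bisulfite conversion
#' rate, discretization fraction, feature-level coverage, M-bias profile,
#' saturation curve, and methylation / CpG-density histograms. When
#' subsampling is enabled, site-level metrics are computed on a uniform
#' random subsample drawn first. A failing or undefined component never
#' aborts the summary: the field is set to `NA` and its name recorded in
#' `flags`.
#'
#' @param records CpG record table for the sample.
#' @param reads Optional call-read table (needed for read counts, M-bias and
#'   conversion rate).
#' @param features Optional named list of interval tables, one per feature
#'   set (e.g. `list(promoters = ..., cpg_islands = ...)`).
#' @param reference_cpgs Optional named list of sorted reference CpG
#'   positions per chromosome (needed for the density metric).
#' @param config A [qc_config()].
#' @param sample_id Sample identifier recorded in the summary.
#' @return Object of class `qc_summary`.
#' @export
compute_qc_summary <- function(records, reads = NULL, features = NULL,
                               reference_cpgs = NULL, config = qc_config(),
                               sample_id = "sample") {
  validate_cpg_records(records)
  flags <- character()
  flag_na <- function(name, expr) {
    v <- tryCatch(suppressWarnings(expr), error = function(e) NA)
    if (length(v) == 1L && is.na(v)) flags <<- c(flags, name)
    v
  }

  used <- records
  if (config$subsample && nrow(records) > config$subsample_n) {
    used <- subsample_sites(records, config$subsample_n, seed = config$seed)
  }

  rm_counts <- if (is.null(reads)) {
    flags <- c(flags, "reads_mapped", "reads_unmapped")
    list(mapped = NA_integer_, unmapped = NA_integer_)
  } else read_metrics(reads)

  conv <- if (is.null(reads)) {
    flags <- c(flags, "conversion_rate")
    NA_real_
  } else flag_na("conversion_rate", bisulfite_conversion_rate(reads))

  feat_cov <- if (is.null(features)) {
    NULL
  } else {
    vapply(names(features), function(nm) {
      flag_na(paste0("feature_coverage.", nm),
              feature_coverage(used, features[[nm]]))
    }, numeric(1))
  }

  dens <- if (is.null(reference_cpgs)) {
    NULL
  } else {
    tryCatch(cpg_density_distribution(used, reference_cpgs,
                                      config$density_window),
             error = function(e) {
               flags <<- c(flags, "cpg_density")
               NULL
             })
  }

  structure(list(
    sample_id = sample_id,
    reads_mapped = rm_counts$mapped,
    reads_unmapped = rm_counts$unmapped,
    cpgs_at_threshold = {
      thr <- cpg_coverage_count(used, config$min_cov_thresholds)
      names(thr) <- as.character(config$min_cov_thresholds)
      thr
    },
    mean_beta = flag_na("mean_beta", {
      b <- site_beta(used)
      if (all(is.na(b))) NA_real_ else mean(b, na.rm = TRUE)
    }),
    conversion_rate = conv,
    discretization_fraction = flag_na(
      "discretization_fraction",
      discretization_fraction(used, config$disc_min_cov,
                              config$disc_low, config$disc_high)
    ),
    feature_coverage = feat_cov,
    mbias = if (is.null(reads)) NULL else mbias_profile(reads),
    saturation = saturation_curve(used, config$saturation_fractions,
                                  config$saturation_min_cov,
                                  seed = config$seed),
    methylation_histogram = methylation_distribution(used,
                                                     config$hist_min_cov,
                                                     config$n_bins),
    cpg_density_histogram = if (is.null(dens)) NULL else dens$histogram,
    subsampled = nrow(used) < nrow(records),
    n_sites_used = nrow(used),
    n_sites_total = nrow(records),
    flags = flags,
    config = unclass(config)
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("QC summary for sample '", x$sample_id, "'\n", sep = "")
  cat("  reads mapped/unmapped: ", x$reads_mapped, " / ", x$reads_unmapped,
      "\n", sep = "")
  cat("  sites used: ", x$n_sites_used, " of ", x$n_sites_total,
      if (x$subsampled) " (subsampled)", "\n", sep = "")
  thr <- x$cpgs_at_threshold
  cat("  CpGs at coverage >= {", paste(names(thr), collapse = ","), "}: ",
      paste(thr, collapse = ", "), "\n", sep = "")
  cat("  mean beta: ", fmt_num(x$mean_beta),
      "; conversion rate: ", fmt_num(x$conversion_rate),
      "; non-binary fraction: ", fmt_num(x$discretization_fraction), "\n",
      sep = "")
  if (length(x$flags)) {
    cat("  undefined metrics: ", paste(x$flags, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

# Scalar fields exposed to aggregation metadata and report tables, in stable
# column order.
qc_scalar_fields <- function(summary) {
  out <- list(
    sample_id = summary$sample_id,
    reads_mapped = summary$reads_mapped,
    reads_unmapped = summary$reads_unmapped,
    mean_beta = summary$mean_beta,
    conversion_rate = summary$conversion_rate,
    discretization_fraction = summary$discretization_fraction,
    subsampled = summary$subsampled,
    n_sites_used = summary$n_sites_used,
    n_sites_total = summary$n_sites_total
  )
  thr <- summary$cpgs_at_threshold
  for (nm in names(thr)) {
    out[[paste0("cpgs_cov_ge_", nm)]] <- unname(thr[nm])
  }
  for (nm in names(summary$feature_coverage)) {
    out[[paste0("feature_coverage_", nm)]] <-
      unname(summary$feature_coverage[nm])
  }
  out
}

#' Write / read a QC summary as JSON
#'
#' The flat JSON serialization is the interchange format between the
#' per-sample QC stage and the aggregation / report stages. Serialization is
#' deterministic: identical summaries produce byte-identical files.
#'
#' @param summary A `qc_summary`.
#' @param path Output path (`.json`).
#' @return `path` invisibly; `read_qc_summary()` returns the `qc_summary`.
#' @export
write_qc_summary <- function(summary, path) {
  stopifnot(inherits(summary, "qc_summary"))
  x <- unclass(summary)
  x$cpgs_at_threshold <- as.list(x$cpgs_at_threshold)
  if (!is.null(x$feature_coverage)) {
    x$feature_coverage <- as.list(x$feature_coverage)
  }
  if (!is.null(x$mbias)) x$mbias <- lapply(unclass(x$mbias), identity)
  x$saturation <- as.data.frame(unclass(x$saturation))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                           null = "null", dataframe = "columns",
                           pretty = TRUE)
  write_text_lines(as.character(json), path)
}

#' @rdname write_qc_summary
#' @export
read_qc_summary <- function(path) {
  x <- jsonlite::fromJSON(paste(read_text_lines(path), collapse = "\n"),
                          simplifyVector = TRUE)
  x$cpgs_at_threshold <- unlist(x$cpgs_at_threshold)
  if (!is.null(x$feature_coverage)) {
    x$feature_coverage <- unlist(x$feature_coverage)
  }
  if (!is.null(x$mbias)) {
    x$mbias <- structure(lapply(x$mbias, as.data.frame),
                         class = "mbias_profile")
  }
  x$saturation <- structure(as.data.frame(x$saturation),
                            class = c("saturation_curve", "data.frame"))
  x$methylation_histogram <- as.data.frame(x$methylation_histogram)
  if (!is.null(x$cpg_density_histogram)) {
    x$cpg_density_histogram <- as.data.frame(x$cpg_density_histogram)
  }
  if (is.null(x$flags)) x$flags <- character()
  x$flags <- as.character(x$flags)
  # JSON null (undefined metric) comes back as NULL; restore typed NAs
  for (nm in c("reads_mapped", "reads_unmapped")) {
    if (is.null(x[[nm]])) x[[nm]] <- NA_integer_
  }
  for (nm in c("mean_beta", "conversion_rate", "discretization_fraction")) {
    if (is.null(x[[nm]])) x[[nm]] <- NA_real_
  }
  structure(x, class = "qc_summary")
}
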