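test_that("read metrics partition primary reads by mapped flag", {
  reads <- methylation_call_reads(
    read_id = paste0("r", 1:5),
    mate = rep("unpaired", 5),
    calls = c("Z", "z", ".", "", ""),
    mapped = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  expect_equal(read_metrics(reads), list(mapped = 3L, unmapped = 2L))
  empty <- methylation_call_reads()
  expect_equal(read_metrics(empty), list(mapped = 0L, unmapped = 0L))
})

test_that("covered-CpG counts respect the threshold", {
  rec <- cpg_records(rep("chr1", 3), c(0L, 10L, 20L),
                     c(1L, 2L, 5L), c(0L, 1L, 5L)) # coverages 1, 3, 10
  expect_equal(cpg_coverage_count(rec, 3L), 2L)
  expect_equal(cpg_coverage_count(rec, 1L), 3L)
  expect_equal(cpg_coverage_count(rec, 11L), 0L)
  expect_equal(cpg_coverage_count(rec, c(1L, 3L)), c(`1` = 3L, `3` = 2L))
  expect_error(cpg_coverage_count(rec, 0L), "min_cov")
})

test_that("M-bias tallies CpG calls by read position and mate", {
  reads <- methylation_call_reads(
    read_id = c("a", "b"), mate = c("R1", "R1"),
    calls = c("ZZ", "Zz"), mapped = c(TRUE, TRUE)
  )
  prof <- mbias_profile(reads)
  expect_named(prof, "R1")
  expect_equal(prof$R1$fraction, c(1.0, 0.5))
  expect_equal(prof$R1$count_meth, c(2L, 1L))

  # reads without CpG calls give an all-undefined profile
  none <- methylation_call_reads("a", "R2", "hHx.", TRUE)
  expect_true(all(is.na(mbias_profile(none)$R2$fraction)))
})

test_that("M-bias is flat for a position-independent landscape", {
  cfg <- simulation_config(n_chroms = 1L, n_sites = 100L, depth_mean = 10,
                           fixed_methylation = 0.7,
                           conversion_efficiency = 1, paired = FALSE,
                           prop_unmapped = 0, seed = 11L)
  sim <- simulate_sample(cfg, simulate_reference(cfg))
  prof <- mbias_profile(sim$reads)$unpaired
  n <- prof$count_meth + prof$count_unmeth
  ok <- n > 0
  se <- sqrt(0.7 * 0.3 / n[ok])
  expect_true(all(abs(prof$fraction[ok] - 0.7) <= 4 * se))
})

test_that("saturation thinning is nested, monotone, exact at f = 1", {
  withr::with_seed(5, {
    rec <- cpg_records(rep("chr1", 500), seq_len(500) * 10L,
                       rpois(500, 4), rpois(500, 4))
  })
  for (seed in c(1L, 2L, 99L)) {
    sc <- saturation_curve(rec, min_cov = 2L, seed = seed)
    expect_false(is.unsorted(sc$covered_cpgs))
    expect_equal(sc$covered_cpgs[nrow(sc)], cpg_coverage_count(rec, 2L))
  }
  # bit-reproducible for a fixed seed
  expect_identical(saturation_curve(rec, seed = 3L),
                   saturation_curve(rec, seed = 3L))
  expect_error(saturation_curve(rec, fractions = c(0, 0.5)), "\\(0, 1\\]")
  expect_error(saturation_curve(rec, fractions = c(0.5, 0.2)), "increasing")
})

test_that("saturation matches the binomial expectation on uniform coverage", {
  n <- 20000L
  rec <- cpg_records(rep("chr1", n), seq_len(n) * 2L,
                     rep(1L, n), rep(0L, n))
  sc <- saturation_curve(rec, fractions = c(0.5, 1), min_cov = 1L,
                         seed = 21L)
  # every site has coverage 1, so covered count at f is Binomial(n, f)
  se <- sqrt(n * 0.25)
  expect_lt(abs(sc$covered_cpgs[1] - 0.5 * n), 4 * se)
  expect_equal(sc$covered_cpgs[2], n)
})

test_that("discretization fraction counts strictly intermediate betas", {
  rec <- function(betas, cov = 10L) {
    cpg_records(rep("chr1", length(betas)), seq_along(betas),
                as.integer(round(betas * cov)),
                as.integer(cov - round(betas * cov)))
  }
  expect_equal(discretization_fraction(rec(c(0, 1, 1, 0)), min_cov = 1L), 0)
  expect_equal(discretization_fraction(rec(rep(0.5, 4)), min_cov = 1L), 1)
  # hand enumeration: of {0, 0.5, 1, 0.3}, the values 0.5 and 0.3 lie in
  # the open interval (0.1, 0.9)
  expect_equal(discretization_fraction(rec(c(0, 0.5, 1, 0.3)), min_cov = 1L,
                                       low = 0.1, high = 0.9), 0.5)
  # no qualifying site -> undefined
  expect_true(is.na(discretization_fraction(rec(c(0, 1)), min_cov = 99L)))
  expect_error(discretization_fraction(rec(0.5), low = 0.9, high = 0.1),
               "low < high")
})

test_that("feature coverage counts features with >= 1 covered CpG", {
  rec <- cpg_records(c("chr1", "chr1"), c(50L, 1000L), c(1L, 0L),
                     c(0L, 0L)) # second site has coverage 0
  feats <- genomic_intervals(c("chr1", "chr1"), c(0L, 900L),
                             c(100L, 1100L))
  expect_equal(feature_coverage(rec, feats), 0.5)
  # half-open: a site at the interval end is outside
  edge <- genomic_intervals("chr1", 0L, 50L)
  expect_equal(feature_coverage(rec, edge), 0)
  expect_true(is.na(feature_coverage(rec, genomic_intervals())))
})

test_that("feature coverage equals the quadratic brute-force oracle", {
  withr::with_seed(1234, {
    for (k in 1:25) {
      inst <- random_instance(n_sites = sample(200:2000, 1),
                              n_features = sample(20:300, 1))
      expect_equal(feature_coverage(inst$records, inst$features),
                   brute_feature_coverage(inst$records, inst$features))
    }
  })
})

test_that("conversion rate pools converted non-CpG calls", {
  reads <- methylation_call_reads(
    read_id = c("a", "b"), mate = c("R1", "R2"),
    calls = c(strrep("h", 98), strrep("H", 2)), mapped = c(TRUE, TRUE)
  )
  expect_equal(bisulfite_conversion_rate(reads), 0.98)
  all_low <- methylation_call_reads("a", "R1", "hhxx", TRUE)
  expect_equal(bisulfite_conversion_rate(all_low), 1)
  cpg_only <- methylation_call_reads("a", "R1", "Zz..", TRUE)
  expect_true(is.na(bisulfite_conversion_rate(cpg_only)))
})

test_that("conversion-rate error shrinks with call count (consistency)", {
  cfg <- function(n) simulation_config(n_chroms = 1L, n_sites = n,
                                       depth_mean = 5,
                                       conversion_efficiency = 0.98,
                                       non_cpg_per_read = 10,
                                       prop_unmapped = 0, seed = 31L)
  errs <- vapply(c(40L, 4000L), function(n) {
    cc <- cfg(n)
    sim <- simulate_sample(cc, simulate_reference(cc))
    abs(bisulfite_conversion_rate(sim$reads) - 0.98)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.005)
})

test_that("methylation histogram conserves counts with closed last bin", {
  rec <- cpg_records(rep("chr1", 2), c(1L, 2L), c(0L, 4L), c(4L, 0L))
  h <- methylation_distribution(rec, n_bins = 2L)
  expect_equal(h$count, c(1L, 1L))
  withr::with_seed(8, {
    n <- 300
    rr <- cpg_records(rep("chr1", n), seq_len(n), rpois(n, 3), rpois(n, 3))
  })
  h2 <- methylation_distribution(rr, min_cov = 2L, n_bins = 7L)
  expect_equal(sum(h2$count), cpg_coverage_count(rr, 2L))
})

test_that("histogram of a deep-coverage beta-mixture matches the truth", {
  n <- 20000L
  mix <- list(weights = c(0.25, 0.75), alpha = c(1, 9), beta = c(9, 1))
  cfg <- simulation_config(n_chroms = 1L, chrom_length = 3e6,
                           n_sites = n, depth_mean = 400,
                           methylation = mix, conversion_efficiency = 1,
                           seed = 77L)
  sim <- simulate_sample(cfg, simulate_reference(cfg), emit_reads = FALSE)
  h <- methylation_distribution(sim$records, min_cov = 50L, n_bins = 10L)
  obs <- h$count / sum(h$count)
  # oracle: sample directly from the mixture, bin the same way
  truth_draw <- withr::with_seed(78L, {
    comp <- sample.int(2L, 2e5, replace = TRUE, prob = mix$weights)
    rbeta(2e5, mix$alpha[comp], mix$beta[comp])
  })
  bin <- findInterval(truth_draw, seq(0, 1, length.out = 11L),
                      rightmost.closed = TRUE)
  expected <- tabulate(bin, 10L) / 2e5
  expect_lt(sum(abs(obs - expected)) / 2, 0.05) # total-variation distance
})

test_that("CpG density uses an inclusive, self-counting window", {
  rec <- cpg_records("chr1", 500L, 1L, 0L)
  # isolated site: only itself within the window
  d1 <- cpg_density_distribution(rec, list(chr1 = 500L), window = 100L)
  expect_equal(d1$density, 1L)
  # uniformly spaced reference every 10 bp, window 50 -> 11 for an interior
  # site (self + 5 on each side)
  ref <- list(chr1 = seq(0L, 2000L, by = 10L))
  d2 <- cpg_density_distribution(rec, ref, window = 50L)
  expect_equal(d2$density, 11L)
  # missing chromosome is skipped and tallied
  off <- cpg_records("chrUn", 5L, 1L, 0L)
  d3 <- cpg_density_distribution(off, ref, window = 50L)
  expect_equal(d3$n_skipped, 1L)
  expect_length(d3$density, 0L)
})

test_that("CpG density equals the quadratic all-pairs oracle", {
  withr::with_seed(99, {
    rec <- cpg_records(
      chrom = sample(c("chr1", "chr2"), 400, replace = TRUE),
      pos = sample.int(20000L, 400, replace = TRUE) - 1L,
      count_meth = rpois(400, 1), count_unmeth = rpois(400, 1)
    )
    ref <- list(chr1 = sort(sample.int(20000L, 800)) - 1L,
                chr2 = sort(sample.int(20000L, 300)) - 1L)
  })
  d <- cpg_density_distribution(rec, ref, window = 75L)
  expect_equal(sort(d$density), sort(brute_cpg_density(rec, ref, 75L)))
})

test_that("site subsampling is uniform, order-preserving, reproducible", {
  withr::with_seed(3, {
    n <- 5000L
    rec <- cpg_records(rep("chr1", n), seq_len(n) * 3L, rpois(n, 5),
                       rpois(n, 5))
  })
  sub <- subsample_sites(rec, 500L, seed = 41L)
  expect_equal(nrow(sub), 500L)
  expect_false(is.unsorted(sub$pos))
  expect_identical(sub, subsample_sites(rec, 500L, seed = 41L))
  expect_false(identical(sub, subsample_sites(rec, 500L, seed = 42L)))
  # n >= total is the identity
  expect_identical(subsample_sites(rec, n, seed = 1L), rec)
  expect_equal(nrow(subsample_sites(rec, 1L, seed = 1L)), 1L)
  # a 10% subsample estimates the full-data mean beta
  full_beta <- mean(site_beta(rec), na.rm = TRUE)
  sub_beta <- mean(site_beta(sub), na.rm = TRUE)
  se <- sd(site_beta(rec), na.rm = TRUE) / sqrt(500) * sqrt(1 - 500 / n)
  expect_lt(abs(sub_beta - full_beta), 4 * se)
})

test_that("the QC summary populates every panel and never aborts", {
  cfg <- simulation_config(n_chroms = 1L, n_sites = 400L, seed = 13L)
  ref <- simulate_reference(cfg)
  sim <- simulate_sample(cfg, ref)
  feats <- genomic_intervals(rep("chr1", 5), (0:4) * 10000L,
                             (0:4) * 10000L + 2000L, paste0("f", 1:5))
  s <- compute_qc_summary(sim$records, reads = sim$reads,
                          features = list(promoters = feats),
                          reference_cpgs = ref$cpg,
                          config = qc_config(seed = 5L),
                          sample_id = "sim1")
  expect_s3_class(s, "qc_summary")
  expect_equal(s$reads_mapped + s$reads_unmapped, nrow(sim$reads))
  expect_true(all(s$cpgs_at_threshold >= 0))
  fracs <- c(s$conversion_rate, s$discretization_fraction,
             s$feature_coverage, s$mean_beta)
  expect_true(all(is.na(fracs) | (fracs >= 0 & fracs <= 1)))
  expect_equal(s$n_sites_used, 400L)
  expect_false(s$subsampled)

  # empty input: zero counts, undefined fractions flagged, no error
  s0 <- compute_qc_summary(cpg_records(), sample_id = "empty")
  expect_equal(unname(s0$cpgs_at_threshold), c(0L, 0L, 0L))
  expect_true(is.na(s0$mean_beta))
  expect_true("discretization_fraction" %in% s0$flags)
})

test_that("subsampling off vs n >= total yields identical summaries", {
  cfg <- simulation_config(n_chroms = 1L, n_sites = 200L, seed = 19L)
  sim <- simulate_sample(cfg, simulate_reference(cfg), emit_reads = FALSE)
  a <- compute_qc_summary(sim$records, config = qc_config(seed = 2L))
  b <- compute_qc_summary(sim$records,
                          config = qc_config(subsample = TRUE,
                                             subsample_n = 1e6, seed = 2L))
  a$config <- b$config <- NULL
  expect_identical(a, b)
})

test_that("QC summaries round-trip through their JSON serialization", {
  cfg <- simulation_config(n_chroms = 1L, n_sites = 150L, seed = 23L)
  ref <- simulate_reference(cfg)
  sim <- simulate_sample(cfg, ref)
  s <- compute_qc_summary(sim$records, reads = sim$reads,
                          reference_cpgs = ref$cpg, sample_id = "rt")
  f <- withr::local_tempfile(fileext = ".json")
  write_qc_summary(s, f)
  back <- read_qc_summary(f)
  expect_equal(back$sample_id, "rt")
  expect_equal(back$cpgs_at_threshold, s$cpgs_at_threshold)
  expect_equal(back$conversion_rate, s$conversion_rate)
  expect_equal(back$saturation$covered_cpgs, s$saturation$covered_cpgs)
  expect_equal(back$mbias$R1$fraction, s$mbias$R1$fraction)
  # writing the same summary twice is byte-identical
  f2 <- withr::local_tempfile(fileext = ".json")
  write_qc_summary(s, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})
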