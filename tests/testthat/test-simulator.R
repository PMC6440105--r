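test_that("fixed-spacing references place CpGs deterministically", {
  cfg <- simulation_config(n_chroms = 1L, chrom_length = 100L,
                           cpg_spacing = list(model = "fixed", spacing = 10L),
                           n_sites = 5L, seed = 1L)
  ref <- simulate_reference(cfg)
  expect_equal(ref$cpg$chr1, c(0L, 10L, 20L, 30L, 40L))
  # too many sites for the chromosome
  cfg_big <- simulation_config(n_chroms = 1L, chrom_length = 100L,
                               cpg_spacing = list(model = "fixed",
                                                  spacing = 10L),
                               n_sites = 50L, seed = 1L)
  expect_error(simulate_reference(cfg_big), "cannot fit")
})

test_that("references are reproducible and strictly increasing", {
  cfg <- simulation_config(n_sites = 500L, seed = 9L)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$cpg, r2$cpg)
  expect_identical(r1$non_cpg, r2$non_cpg)
  for (p in c(r1$cpg, r1$non_cpg)) {
    expect_false(is.unsorted(p, strictly = TRUE))
  }
  # non-CpG cytosines avoid CpG dyads (the C and the following G)
  for (ch in names(r1$cpg)) {
    expect_length(intersect(r1$non_cpg[[ch]],
                            c(r1$cpg[[ch]], r1$cpg[[ch]] + 1L)), 0L)
  }
})

test_that("geometric spacing attains the requested mean gap", {
  cfg <- simulation_config(n_chroms = 1L, chrom_length = 3e6,
                           cpg_spacing = list(model = "geometric",
                                              mean_gap = 100),
                           n_sites = 10000L, seed = 3L)
  ref <- simulate_reference(cfg)
  gaps <- diff(ref$cpg$chr1)
  # gap - 1 ~ Geometric with mean 99, so SD of the mean gap is
  # sqrt(mean * (mean + 1)) / sqrt(n)
  se <- sqrt(99 * 100) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 100), 4 * se)
})

test_that("limit cases: perfect conversion with all-or-nothing methylation", {
  base <- list(n_chroms = 1L, n_sites = 60L, depth_mean = 8,
               conversion_efficiency = 1, prop_unmapped = 0, seed = 71L)
  cfg1 <- do.call(simulation_config, c(base, fixed_methylation = 1))
  sim1 <- simulate_sample(cfg1, simulate_reference(cfg1))
  expect_equal(sum(sim1$records$count_unmeth), 0L)
  cpg_calls <- gsub("[^Zz]", "", sim1$reads$calls[sim1$reads$mapped])
  expect_true(all(cpg_calls == "Z"))
  # non-CpG cytosines all converted (lowercase) at efficiency 1
  expect_false(any(grepl("[HX]", sim1$reads$calls)))

  cfg0 <- do.call(simulation_config, c(base, fixed_methylation = 0))
  sim0 <- simulate_sample(cfg0, simulate_reference(cfg0))
  expect_equal(sum(sim0$records$count_meth), 0L)
})

test_that("simulated records follow the stated observation model", {
  # with conversion efficiency e, an unmethylated cytosine reads methylated
  # with probability 1 - e; at p = 0 the pooled methylated fraction over
  # many calls must sit at 1 - e
  cfg <- simulation_config(n_chroms = 1L, n_sites = 5000L, depth_mean = 10,
                           fixed_methylation = 0,
                           conversion_efficiency = 0.95, seed = 83L)
  sim <- simulate_sample(cfg, simulate_reference(cfg), emit_reads = FALSE)
  n_calls <- sum(site_coverage(sim$records))
  frac <- sum(sim$records$count_meth) / n_calls
  se <- sqrt(0.05 * 0.95 / n_calls)
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("emitted reads and emitted records are two views of one sample", {
  cfg <- simulation_config(n_chroms = 2L, n_sites = 200L, seed = 29L)
  sim <- simulate_sample(cfg, simulate_reference(cfg))
  expect_identical(tally_call_reads(sim$reads), covered_sorted(sim$records))
  # and the same holds after a round trip through SAM on disk
  f <- withr::local_tempfile(fileext = ".sam")
  write_methylation_calls(sim$reads, f)
  expect_identical(tally_from_sam(f), covered_sorted(sim$records))
})

test_that("samples are reproducible given (config, seed)", {
  cfg <- simulation_config(n_chroms = 1L, n_sites = 100L, seed = 37L)
  ref <- simulate_reference(cfg)
  s1 <- simulate_sample(cfg, ref, seed = 5L)
  s2 <- simulate_sample(cfg, ref, seed = 5L)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$reads, s2$reads)
  s3 <- simulate_sample(cfg, ref, seed = 6L)
  expect_false(identical(s1$records, s3$records))
})

test_that("cohort samples share the reference but are independent draws", {
  cfg <- simulation_config(n_chroms = 1L, n_sites = 90L, seed = 43L)
  cohort <- simulate_cohort(cfg, 3L, emit_reads = FALSE)
  expect_length(cohort$samples, 3L)
  recs <- lapply(cohort$samples, `[[`, "records")
  expect_identical(recs[[1]][c("chrom", "pos")], recs[[2]][c("chrom", "pos")])
  expect_false(identical(recs[[1]]$count_meth, recs[[2]]$count_meth))
})

test_that("reference CpG lists round-trip through TSV", {
  cfg <- simulation_config(n_chroms = 2L, n_sites = 50L, seed = 67L)
  ref <- simulate_reference(cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reference_cpgs(ref, f)
  back <- read_reference_cpgs(f)
  expect_identical(back[names(ref$cpg)], ref$cpg)
})
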