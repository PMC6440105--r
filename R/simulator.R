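#' Configuration for the bisulfite data simulator
#'
#' Describes a synthetic methylation landscape and sequencing process with
#' known ground truth, so every QC metric and the aggregation step can be
#' validated without external data. Defaults emulate a small mammalian-like
#' WGBS sample: CpGs spaced geometrically with a ~100 bp mean gap (roughly
#' genome-wide CpG density), a bimodal methylome with ~75% of CpGs in a
#' hypermethylated mode, Poisson(10) per-site depth, 100 bp reads, and a
#' bisulfite conversion efficiency of 0.99.
#'
#' @param n_chroms Number of chromosomes (`chr1`, `chr2`, ...).
#' @param chrom_length Length of each chromosome (bp).
#' @param cpg_spacing List: `model` is `"fixed"` or `"geometric"`; `fixed`
#'   uses `spacing` bp between CpGs starting at 0; `geometric` draws gaps
#'   `1 + Geometric` with the given `mean_gap`.
#' @param n_sites Total CpG count across chromosomes (split evenly). For the
#'   geometric model, `NULL` fills each chromosome.
#' @param methylation Two-component beta mixture for per-site methylation:
#'   `weights` (hypo, hyper) and shape vectors `alpha`, `beta`.
#' @param fixed_methylation If non-`NULL`, every site gets this methylation
#'   probability instead of a mixture draw (position-independent landscape,
#'   used e.g. for M-bias flatness checks).
#' @param depth_mean Poisson mean per-site sequencing depth.
#' @param read_length Read length (bp); each simulated read carries one CpG
#'   call.
#' @param conversion_efficiency Probability an unmethylated cytosine is
#'   converted (reads as T). Methylated cytosines are protected from
#'   conversion and always read as C.
#' @param non_cpg_per_read Poisson mean number of non-CpG cytosines (CHH/CHG)
#'   per read.
#' @param non_cpg_gap Mean gap (bp) between non-CpG cytosines in the
#'   simulated reference.
#' @param prop_unmapped Fraction of all primary reads that fail to align.
#' @param paired Emit paired reads (mates assigned R1/R2 at random) or
#'   unpaired reads.
#' @param seed Base seed; all simulator draws are bit-reproducible given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_chroms = 2L, chrom_length = 1e6,
                              cpg_spacing = list(model = "geometric",
                                                 mean_gap = 100),
                              n_sites = 5000L,
                              methylation = list(weights = c(0.25, 0.75),
                                                 alpha = c(1, 9),
                                                 beta = c(9, 1)),
                              fixed_methylation = NULL,
                              depth_mean = 10, read_length = 100L,
                              conversion_efficiency = 0.99,
                              non_cpg_per_read = 20, non_cpg_gap = 10,
                              prop_unmapped = 0.15, paired = TRUE,
                              seed = 1L) {
  stopifnot(
    n_chroms >= 1, chrom_length > 0,
    cpg_spacing$model %in% c("fixed", "geometric"),
    conversion_efficiency >= 0, conversion_efficiency <= 1,
    depth_mean > 0, read_length >= 1, non_cpg_per_read >= 0,
    prop_unmapped >= 0, prop_unmapped < 1
  )
  if (!is.null(fixed_methylation)) {
    stopifnot(fixed_methylation >= 0, fixed_methylation <= 1)
  } else {
    stopifnot(
      length(methylation$weights) == length(methylation$alpha),
      length(methylation$alpha) == length(methylation$beta),
      all(methylation$weights >= 0), sum(methylation$weights) > 0,
      all(methylation$alpha > 0), all(methylation$beta > 0)
    )
  }
  structure(list(
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    cpg_spacing = cpg_spacing, n_sites = if (is.null(n_sites)) NULL else
      as.integer(n_sites),
    methylation = methylation, fixed_methylation = fixed_methylation,
    depth_mean = depth_mean, read_length = as.integer(read_length),
    conversion_efficiency = conversion_efficiency,
    non_cpg_per_read = non_cpg_per_read, non_cpg_gap = non_cpg_gap,
    prop_unmapped = prop_unmapped, paired = isTRUE(paired),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

sim_positions <- function(model, n, chrom_length, spacing = NULL,
                          mean_gap = NULL) {
  if (model == "fixed") {
    pos <- seq(0L, by = as.integer(spacing), length.out = n)
    if (n > 0 && pos[n] >= chrom_length) {
      stop(sprintf("cannot fit %d sites spaced %d bp in %d bp", n,
                   as.integer(spacing), chrom_length), call. = FALSE)
    }
    return(pos)
  }
  # geometric gaps: gap = 1 + Geom(1/mean_gap), so E[gap] = mean_gap
  if (is.null(n)) n <- ceiling(chrom_length / mean_gap * 1.5) + 50L
  gaps <- 1L + stats::rgeom(n, prob = 1 / mean_gap)
  pos <- cumsum(gaps) - 1L
  pos[pos < chrom_length]
}

#' Simulate a reference CpG / non-CpG cytosine map
#'
#' @param config A [simulation_config()].
#' @return List of class `sim_reference` with `cpg` and `non_cpg`: named
#'   lists (per chromosome) of strictly increasing 0-based positions, plus
#'   the config.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    per_chrom <- if (is.null(config$n_sites)) NULL else {
      n <- rep(config$n_sites %/% config$n_chroms, config$n_chroms)
      n[seq_len(config$n_sites %% config$n_chroms)] <-
        n[seq_len(config$n_sites %% config$n_chroms)] + 1L
      n
    }
    cpg <- list()
    non_cpg <- list()
    for (i in seq_along(chroms)) {
      sp <- config$cpg_spacing
      p <- sim_positions(sp$model, per_chrom[i], config$chrom_length,
                         spacing = sp$spacing, mean_gap = sp$mean_gap)
      if (!is.null(per_chrom) && length(p) < per_chrom[i]) {
        stop(sprintf(
          "chromosome %s (%d bp) cannot hold %d CpGs at the requested spacing",
          chroms[i], config$chrom_length, per_chrom[i]), call. = FALSE)
      }
      if (!is.null(per_chrom)) p <- p[seq_len(per_chrom[i])]
      nc <- sim_positions("geometric", NULL, config$chrom_length,
                          mean_gap = config$non_cpg_gap)
      # a CpG occupies its position and the next base (the G); keep non-CpG
      # cytosines off both
      nc <- setdiff(nc, c(p, p + 1L))
      cpg[[chroms[i]]] <- as.integer(p)
      non_cpg[[chroms[i]]] <- as.integer(nc)
    }
    structure(list(cpg = cpg, non_cpg = non_cpg, config = config),
              class = "sim_reference")
  })
}

#' Simulate one bisulfite sample with known truth
#'
#' Per site `i` with true methylation probability `p_i` and depth
#' `d_i ~ Poisson(depth_mean)`, the observed methylated count is
#' `m_i ~ Binomial(d_i, p_i + (1 - p_i) (1 - e))` where `e` is the
#' conversion efficiency: methylated cytosines always read methylated, and
#' an unmethylated cytosine escapes conversion (reads methylated) with
#' probability `1 - e`. Emitted call reads are exactly consistent with the
#' emitted counts: each mapped read carries one CpG call (`Z`/`z`) at a
#' uniformly random position within the read, plus Poisson-many non-CpG
#' calls whose case is drawn with the same conversion efficiency
#' (non-CpG cytosines are unmethylated in truth).
#'
#' @param config A [simulation_config()].
#' @param reference A [simulate_reference()] result.
#' @param sample_id Identifier used for read names.
#' @param seed Seed for this sample's draws (defaults to the config seed).
#' @param emit_reads If `FALSE`, skip call-read generation (much faster when
#'   only site-level records are needed).
#' @return List of class `sim_sample`: `records` (CpG record table, sorted),
#'   `reads` (call-read table with `chrom`, `site_pos`, `call_col` anchoring
#'   columns, or `NULL`), and `truth` (data frame `chrom`, `pos`, `p_true`,
#'   `depth` plus attribute `conversion_efficiency`).
#' @export
simulate_sample <- function(config, reference, sample_id = "sample1",
                            seed = config$seed, emit_reads = TRUE) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(reference, "sim_reference"))
  withr::with_seed(as.integer(seed), {
    chrom <- rep(names(reference$cpg), lengths(reference$cpg))
    pos <- unlist(reference$cpg, use.names = FALSE)
    n <- length(pos)
    e <- config$conversion_efficiency
    p_true <- if (!is.null(config$fixed_methylation)) {
      rep(config$fixed_methylation, n)
    } else {
      mx <- config$methylation
      comp <- sample.int(length(mx$weights), n, replace = TRUE,
                         prob = mx$weights)
      stats::rbeta(n, mx$alpha[comp], mx$beta[comp])
    }
    depth <- stats::rpois(n, config$depth_mean)
    q_obs <- p_true + (1 - p_true) * (1 - e)
    m <- stats::rbinom(n, depth, q_obs)
    records <- cpg_records(chrom, pos, m, depth - m)
    truth <- data.frame(chrom = chrom, pos = pos, p_true = p_true,
                        depth = depth, stringsAsFactors = FALSE)
    attr(truth, "conversion_efficiency") <- e

    reads <- NULL
    if (emit_reads) {
      n_reads <- sum(depth)
      site_of <- rep.int(seq_len(n), depth)
      # first m_i of each site's reads methylated: exact count consistency
      meth <- sequence(depth) <= rep.int(m, depth)
      L <- config$read_length
      site_pos <- pos[site_of]
      call_col <- pmin(sample.int(L, n_reads, replace = TRUE),
                       site_pos + 1L)
      mat <- matrix(".", nrow = n_reads, ncol = L)
      n_nc <- pmin(stats::rpois(n_reads, config$non_cpg_per_read), L - 1L)
      tot_nc <- sum(n_nc)
      if (tot_nc > 0) {
        rows <- rep.int(seq_len(n_reads), n_nc)
        cols <- sample.int(L, tot_nc, replace = TRUE)
        ctx <- sample(c("h", "x"), tot_nc, replace = TRUE,
                      prob = c(0.7, 0.3))
        unconverted <- stats::runif(tot_nc) > e
        ctx[unconverted] <- toupper(ctx[unconverted])
        mat[cbind(rows, cols)] <- ctx
      }
      # CpG call written last so it wins any position collision
      mat[cbind(seq_len(n_reads), call_col)] <- ifelse(meth, "Z", "z")
      calls <- do.call(paste0, lapply(seq_len(L), function(j) mat[, j]))
      n_unmapped <- round(n_reads * config$prop_unmapped /
                            (1 - config$prop_unmapped))
      mate_pool <- if (config$paired) c("R1", "R2") else "unpaired"
      n_tot <- n_reads + n_unmapped
      mate <- if (config$paired) {
        sample(mate_pool, n_tot, replace = TRUE)
      } else rep("unpaired", n_tot)
      reads <- methylation_call_reads(
        read_id = sprintf("%s_r%07d", sample_id, seq_len(n_tot)),
        mate = mate,
        calls = c(calls, rep("", n_unmapped)),
        mapped = c(rep(TRUE, n_reads), rep(FALSE, n_unmapped))
      )
      reads$chrom <- c(chrom[site_of], rep(NA_character_, n_unmapped))
      reads$site_pos <- c(site_pos, rep(NA_integer_, n_unmapped))
      reads$call_col <- c(call_col, rep(NA_integer_, n_unmapped))
    }
    structure(list(records = records, reads = reads, truth = truth,
                   sample_id = sample_id),
              class = "sim_sample")
  })
}

#' Tally CpG calls of simulated reads back onto sites
#'
#' Reconstructs per-site methylated/unmethylated counts from the call reads
#' using their anchoring columns — the independent second view used to check
#' internal consistency of the simulator's two outputs.
#'
#' @param reads Call-read table with `chrom`, `site_pos`, `call_col`.
#' @return CpG record table, sorted by (chrom, pos).
#' @export
tally_call_reads <- function(reads) {
  stopifnot(all(c("chrom", "site_pos", "call_col") %in% names(reads)))
  r <- reads[reads$mapped, , drop = FALSE]
  call <- substr(r$calls, r$call_col, r$call_col)
  stopifnot(all(call %in% c("Z", "z")))
  key <- paste0(r$chrom, ":", r$site_pos)
  meth <- tapply(call == "Z", key, sum)
  tot <- tapply(rep(1L, nrow(r)), key, sum)
  keys <- names(meth)
  chrom <- sub(":[0-9]+$", "", keys)
  pos <- as.integer(sub("^.*:", "", keys))
  o <- site_order(chrom, pos)
  cpg_records(chrom[o], pos[o], as.integer(meth[keys][o]),
              as.integer(tot[keys] - meth[keys])[o])
}

#' Simulate a cohort of samples sharing one reference
#'
#' @param config A [simulation_config()].
#' @param n_samples Number of samples.
#' @param sample_ids Optional ids (default `sample01`, ...).
#' @param emit_reads Passed to [simulate_sample()].
#' @return List of class `sim_cohort` with `reference` and `samples` (list
#'   of `sim_sample`). Sample `k` uses seed `config$seed + k`, so cohorts
#'   are reproducible and samples mutually independent.
#' @export
simulate_cohort <- function(config, n_samples,
                            sample_ids = sprintf("sample%02d",
                                                 seq_len(n_samples)),
                            emit_reads = TRUE) {
  stopifnot(n_samples >= 1, length(sample_ids) == n_samples)
  reference <- simulate_reference(config)
  samples <- lapply(seq_len(n_samples), function(k) {
    simulate_sample(config, reference, sample_id = sample_ids[k],
                    seed = config$seed + k, emit_reads = emit_reads)
  })
  names(samples) <- sample_ids
  structure(list(reference = reference, samples = samples, config = config),
            class = "sim_cohort")
}

#' Write a simulated reference CpG map as TSV
#'
#' @param reference A `sim_reference`.
#' @param path Output TSV (`chrom`, `pos`).
#' @return `path` invisibly; `read_reference_cpgs()` returns the named
#'   per-chromosome sorted position list.
#' @export
write_reference_cpgs <- function(reference, path) {
  chrom <- rep(names(reference$cpg), lengths(reference$cpg))
  pos <- unlist(reference$cpg, use.names = FALSE)
  write_text_lines(c("chrom\tpos", sprintf("%s\t%d", chrom, pos)), path)
}

#' @rdname write_reference_cpgs
#' @export
read_reference_cpgs <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) <= 1L) return(list())
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- as.integer(vapply(parts, `[[`, "", 2L))
  lapply(split(pos, chrom), sort)
}

#' Write one simulated sample to disk
#'
#' Emits the three artifacts the pipeline consumes / checks: a
#' Bismark-dialect coverage file, a SAM file of methylation-call reads, and
#' the ground-truth table.
#'
#' @param sim A `sim_sample`.
#' @param dir Output directory.
#' @param sample_id Basename for the files (defaults to the sample's id).
#' @return Named list of written paths.
#' @export
write_sim_sample <- function(sim, dir, sample_id = sim$sample_id) {
  stopifnot(inherits(sim, "sim_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    coverage = file.path(dir, paste0(sample_id, ".cov")),
    truth = file.path(dir, paste0(sample_id, ".truth.tsv"))
  )
  rec <- sim$records
  o <- site_order(rec$chrom, rec$pos)
  write_bismark_coverage(rec[o, , drop = FALSE], paths$coverage)
  tr <- sim$truth
  write_text_lines(
    c("chrom\tpos\tp_true\tdepth",
      sprintf("%s\t%d\t%s\t%d", tr$chrom, tr$pos, sprintf("%.17g", tr$p_true),
              tr$depth)),
    paths$truth
  )
  if (!is.null(sim$reads)) {
    paths$calls <- file.path(dir, paste0(sample_id, ".sam"))
    write_methylation_calls(sim$reads, paths$calls)
  }
  paths
}
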