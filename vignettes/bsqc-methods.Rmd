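---
title: "bsqc: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bsqc: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsqc)
```

## Scope and workflow

`bsqc` is a quality-control and aggregation toolkit for bisulfite
sequencing DNA methylation data (WGBS, RRBS, hybrid-selection capture, and
single-cell protocols). It consumes the outputs of a bisulfite-aware
aligner — per-CpG coverage files with methylated/unmethylated read counts
(the Bismark six-column dialect) and alignments carrying per-base
methylation-call strings (the `XM`-tag dialect) — and produces, in two
stages that mirror standard preprocessing practice:

1. **Per-sample stage** (`cmd_qc()`): a QC summary covering read mapping
   counts, covered CpGs at coverage thresholds, M-bias profiles, a
   downsampling saturation curve, the methylation discretization fraction,
   feature-level coverage, the bisulfite conversion rate, and methylation /
   CpG-density distributions; plus a bedGraph methylation track per sample.
2. **Aggregation stage** (`cmd_aggregate()`, `cmd_report()`): cohort-level
   methylated-count and coverage matrices annotated with the per-sample QC
   scalars, and plain-text + self-contained HTML reports.

Alignment, trimming and methylation calling are out of scope: the package
starts from aligner outputs. Everything downstream of them is deterministic
given the inputs and a seed, which is part of the package's contract (see
*Determinism*, below).

## The metric panel

**Read counts.** Primary alignments partitioned by the mapped flag.
Secondary and supplementary alignments are never counted.

**Covered CpGs.** The number of sites with total coverage at or above each
threshold in `min_cov_thresholds` (defaults 1, 5, 10). Counts are computed
on the (possibly subsampled) site table, so they are comparable across
samples processed with the same configuration.

**M-bias.** At each read position, the fraction of CpG calls that are
methylated (`Z` among `Z`+`z`), tallied separately for R1 and R2 mates.
Methylation state has no reason to depend on position within a read, so a
well-behaved library yields a flat profile; systematic deviation at read
ends is the signature of end-repair or trimming artifacts. Positions with
no CpG call have an undefined (NA) fraction rather than zero.

**Downsampling saturation curve.** How many CpGs would remain covered if
only a fraction $f$ of the reads had been sequenced. Coverage files carry no
read identity, so rather than resampling raw reads the per-site coverages
are *binomially thinned*: a site with coverage $n$ has thinned coverage
$\mathrm{Binomial}(n, f)$. Thinning is *nested* — going from fraction
$f_{k+1}$ down to $f_k$ re-thins the already-thinned counts with probability
$f_k/f_{k+1}$ — which makes the retained reads at a smaller fraction a
subset of those at a larger fraction. Two consequences are guaranteed by
construction, not just in expectation: each realized curve is nondecreasing
in $f$, and $f = 1$ reproduces the exact covered-site count. A curve still
rising at $f = 1$ means deeper sequencing would reveal additional CpGs. The
default grid is $\{0.01, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1\}$ with
`min_cov = 1`.

**Discretization fraction.** The fraction of sites (with coverage $\ge$
`disc_min_cov`, default 5) whose methylation estimate lies strictly inside
`(disc_low, disc_high)` (defaults 0.1, 0.9). In single cells each covered
allele is essentially fully methylated or unmethylated, so a large fraction
of intermediate values flags technical noise. The cutoffs are explicit
configuration, echoed into every output — they are sensible defaults, not a
claim of equivalence to any other tool's cutoffs. The coverage threshold
matters: at coverage 2–4, intermediate betas arise from sampling alone.

**Feature-level coverage.** The fraction of features (promoters, CpG
islands, ... supplied as BED) containing at least one covered CpG,
computed by binary search over sorted site positions per chromosome.
Intervals are half-open (`[start, end)`, the BED convention); a site at
`end` is outside.

**Bisulfite conversion rate.** Non-CpG cytosines are essentially
unmethylated in most mammalian tissues, so the fraction of CHH/CHG calls
read as converted, $(\#h + \#x) / (\#h + \#x + \#H + \#X)$, estimates the
chemical conversion efficiency and should be close to 1. CHG and CHH are
pooled (they carry the same information for this purpose); unknown-context
calls (`U`/`u`) are excluded because their context, and hence their expected
methylation, is unknown. Spike-in controls are out of scope.

**Methylation distribution.** A histogram of per-site betas over sites with
coverage $\ge$ `hist_min_cov`, on `n_bins` equal-width bins of $[0,1]$,
left-closed with a right-closed last bin so every qualifying site lands in
exactly one bin. Sample-to-sample deviations in this distribution flag
technical artifacts.

**CpG density distribution.** For each covered site, the number of
reference CpGs within ±`density_window` bp (default 100), *including the
site itself* — self-inclusion makes the isolated-site case unambiguous
(density 1, never 0). Similar distributions across samples indicate
coverage of similar genomic regions, which matters most for
enrichment-based protocols.

## Site subsampling

Metric cost scales with the number of sites, and for a human-scale
methylome (~28 million CpGs) a uniform random subsample as small as one
million sites gives unbiased and stable QC estimates. `subsample_sites()`
draws without replacement, preserves genomic order, and is deterministic
given its seed; `qc_config(subsample = TRUE)` applies it before all
site-level metrics (read-level metrics — M-bias, conversion rate — always
use all reads). The default subsample size is 1,000,000 sites and the
feature is off by default, so small datasets are never silently subsampled.
The summary records whether subsampling happened and how many sites were
used.

## Aggregation

`aggregate_samples()` builds the cohort matrices over the **union** of the
per-sample site sets (an intersection filter can be applied downstream; the
union loses nothing and keeps every input read accounted for — the column
sums of the coverage matrix equal the per-sample total coverages exactly).
Missing (site, sample) cells are encoded as coverage 0, not a sentinel:
counts are the primitive, integer matrices stay integer, and a beta at
coverage 0 is simply undefined downstream.

Two interchangeable on-disk backends are provided. The `text` backend
writes plain TSVs (sites, M, Cov, metadata) for portability and exact
diffability. The `chunked` backend writes column-major chunks of 10,000
sites × all samples plus a JSON manifest, so per-sample streaming touches a
bounded number of contiguous blocks; the environment provides no R
interface to a standard hierarchical array container, so the chunk format
is package-defined (uncompressed R serialization), with logical-content
equivalence to the text backend under test. Metadata column types are
recorded in the manifest so round-trips are type-exact.

## The simulator: a stated world

The simulator exists so that every metric and the aggregation step can be
validated against *known truth* without downloads. Its defaults describe
one fixed, documented world:

| parameter | default | why |
|---|---|---|
| CpG spacing | geometric gaps, mean 100 bp | genome-wide human CpG density is roughly one per hundred bases |
| methylation landscape | 25% Beta(1,9) + 75% Beta(9,1) | the bimodal mammalian methylome: most CpGs strongly methylated, a hypomethylated minority (islands/regulatory), mean ≈ 0.7 |
| per-site depth | Poisson(10) | a modest WGBS-like depth where coverage thresholds and saturation both have visible structure |
| read length | 100 bp | standard short-read length |
| conversion efficiency | 0.99 | typical of a successful bisulfite conversion ("close to 100%") |
| non-CpG cytosines per read | Poisson(20) | order-of-magnitude count of CHH/CHG positions in a 100 bp mammalian read |
| unmapped fraction | 0.15 | bisulfite alignment rates run well below ordinary DNA-seq |

**Observation model.** Per site $i$ with true methylation probability
$p_i$ and depth $d_i \sim \mathrm{Poisson}(\lambda)$, the observed
methylated count is

$$m_i \sim \mathrm{Binomial}\!\left(d_i,\; p_i + (1 - p_i)(1 - e)\right),$$

where $e$ is the conversion efficiency. The asymmetry is deliberate and
chemical: bisulfite conversion only acts on *unmethylated* cytosines, so a
methylated cytosine always reads methylated, while an unmethylated one
escapes conversion (reads methylated) with probability $1 - e$. At $e = 1$
the observed rate is exactly $p_i$. Non-CpG cytosines are unmethylated in
truth and read methylated with the same escape probability — a single noise
knob, shared between contexts, keeps parameter-recovery tests
interpretable. Sequencing error beyond conversion failure is deliberately
not modelled.

**Two consistent views.** Each simulated sample is emitted both as count
records and as call reads (each mapped read carries exactly one CpG call at
a uniformly random in-read position, anchored to genomic coordinates).
The methylated read assignment is exact, not re-sampled, so tallying the
call reads reproduces the count records *identically* — this internal
consistency is itself under test, and it is what lets read-level metrics
(M-bias, conversion rate) and site-level metrics be validated against the
same truth.

**What the simulator does not emulate** — and therefore what a green test
does *not* establish: PCR duplicates and library complexity limits,
sequence-dependent coverage bias (GC, mappability), position-dependent
M-bias artifacts (reads are position-independent by construction, which is
exactly why flatness is testable), strand asymmetries, real read sequences
and quality strings, and single-cell sparsity patterns beyond what low
Poisson depth produces. Tests against simulated data establish that the
*estimators are correct under the stated model*, not that real libraries
are well behaved.

## Numerical and convention choices

- **Coordinates** are 0-based half-open everywhere internally; the
  Bismark coverage dialect (1-based) is converted at the I/O boundary, so
  interval arithmetic and BED compatibility need no special cases.
- **Percentage cross-check**: the coverage file's printed percentage is
  recomputed from the counts; disagreement beyond 0.5 percentage points
  warns and the counts win (printed percentages are rounded).
- **Strand-split dialects**: some coverage files report the two cytosines
  of a CpG dyad separately at positions $p$ and $p+1$. An optional merge
  step sums the reverse-strand counts onto the forward cytosine; it is off
  by default because both dialects exist in the wild and the input dialect
  cannot be detected reliably.
- **Tracks** are bedGraph text rather than binary bigwig: bit-exact
  testability and zero binary dependencies; standard converters produce
  bigwig from bedGraph when needed.
- **Undefined metrics** (zero qualifying sites, zero non-CpG calls, empty
  feature set) are `NA` plus an entry in the summary's `flags` field —
  never 0, and never a reason to abort the rest of the summary.
- **Determinism**: every stochastic step (subsampling, saturation
  thinning, simulation) runs under an explicit seed recorded in the output;
  text outputs are written in binary mode with fixed formatting so reruns
  are byte-identical. `cmd_aggregate()` and `cmd_report()` sort samples by
  id, making pipeline output independent of input order; the lower-level
  `aggregate_samples()` preserves caller order (permuting its inputs
  permutes matrix columns correspondingly).
- **Ties and edge cases**: the last histogram bin is right-closed so beta
  = 1 is counted; features are half-open so a site at `end` is outside;
  saturation at $f = 1$ bypasses the RNG entirely and returns the exact
  count.

## Limitations

- The conversion-rate estimator assumes non-CpG methylation is negligible;
  in tissues with appreciable CHH/CHG methylation (e.g. brain, plants) it
  underestimates the true chemical efficiency.
- Binomial thinning approximates read-level downsampling: it ignores the
  (slight) dependence between nearby sites covered by the same read, so
  saturation-curve uncertainty is understated at small fractions.
- The chunked backend is package-specific; it is an on-disk layout for
  streaming, not an interchange format — use the text backend (or export
  from it) to move matrices between tools.
- The union site set can grow large for many deeply-covered WGBS samples;
  matrices are dense in memory. Subsampling helps QC, not aggregation.
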