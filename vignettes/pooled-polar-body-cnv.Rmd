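---
title: "Trisomic-baseline copy-number calling for pooled polar bodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trisomic-baseline copy-number calling for pooled polar bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarploidy)
```

## The problem

Preimplantation genetic testing for aneuploidy (PGT-A) on polar bodies
infers the chromosomal constitution an oocyte passed on by examining the
material it discarded during meiosis. The first polar body carries two
chromatids of each chromosome and the second carries one, so when both are
pooled and amplified together, the *euploid* expectation is **three
chromatids per chromosome** — not the diploid two that essentially all
copy-number software assumes. Every component of this package is built
around that trisomic baseline:

* a low-pass sequencing caller that models binned read counts with a
  hidden Markov model over 0- to 4-somy states and anchors the modal state
  at 3-somy;
* an aCGH classifier whose expected log2 ratios and gain/loss thresholds
  are recomputed for a baseline of 3;
* concordance machinery to compare the two methods call by call;
* a seeded simulator of WGA-distorted coverage and probe profiles that
  supplies ground truth for all of the above.

Material amplified from one or two cells behaves badly: whole-genome
amplification (WGA) produces strong, uneven multiplicative coverage noise,
dropout regions, and "undulating" profiles whose baseline is genuinely
ambiguous. The design choices below exist to cope with exactly these
features.

## The sequencing caller

### Binning and correction

Reads are ingested from BAM/SAM (or a plain TSV of read starts) after
removing unmapped, secondary and supplementary records and any read with
mapping quality below 5. Reads are counted in fixed 100-kb bins; bins with
counts above the 0.9985 quantile or below the 0.1 quantile of the sample's
own genome-wide distribution are masked (type-7 interpolated quantiles; the
definition matters because masking is threshold-sensitive). The same mask
computed on a merged euploid *reference* read set acts as a blacklist, and
the two masks are **intersected**: a bin must be extreme in both the sample
and the euploid reference to be excluded. A union would be wrong here — on
a chromosome with a genuine chromatid loss, the sample's lowest-decile bins
are concentrated on that chromosome, and masking them would erase the
signal being looked for.

Mappability is corrected by variable-width binning: bins are rebuilt so
each contains the same number of reference reads (the median fixed-bin
reference count at the 1-Mb nominal width), with boundaries at midpoints
between reads and terminal bins holding fewer than half the target merged
into their neighbour. Low-mappability territory therefore becomes
genomically wider bins with comparable statistical weight. The reference
should be a merge of several euploid samples (`simulate_reference()` uses
six, mirroring the validating workflow's six samples selected at aCGH
DLRS < 0.7): merging averages away each sample's private WGA noise while
preserving the mappability landscape they share. GC bias is then removed
by a second-degree polynomial fit of count on bin GC, rescaled so the
unmasked mean is preserved exactly; non-positive fitted values are clamped
to the 1st percentile of the positive fit with a warning.

### The hidden Markov model

Emissions are tied negative binomials: a single per-chromatid pair
$(\mu, \sigma^2)$ gives state $s$ mean $s\mu$ and variance $s\sigma^2$,
$s = 1 \dots 4$. Tying is what makes a 3-somy baseline identifiable at low
coverage — with free per-state parameters, a fit that labels everything one
state higher is just as good. Two further states absorb zero-heavy bins:

* **zero-inflation**: a point mass at zero (WGA dropout);
* **0-somy**: NB with mean $\varepsilon\mu$, $\varepsilon = 0.1$ fixed,
  for residual misalignment background. Two point masses at zero would be
  unidentifiable; a small residual mean keeps the states distinct.

The variance is floored at $1.05\mu$ (a valid NB needs variance above the
mean), and corrected counts are rounded before emission evaluation since
the NB is discrete. Baum–Welch runs in log space per chromosome
(chromosomes are independent chains), with closed-form transition and
initial-distribution updates and a numerical update of $(\mu, \sigma^2)$
that is accepted only when it improves the expected complete-data
log-likelihood — a generalised EM step, so the log-likelihood trace is
provably non-decreasing. Iteration stops at a relative gain below `1e-4`
or 500 iterations. Three restarts with jittered transition matrices reduce
(but, faithfully to the data regime, do not eliminate) local optima.

### Baseline anchoring

The known failure mode of these fits is the *baseline shift*: EM converges
with, say, 4-somy modal, and every chromosome is then miscalled by one
chromatid. After decoding, if the modal state by total bp is not 3-somy,
$\mu$ is rescaled by (modal somy)/3 and the model refitted, up to three
times. If anchoring still fails the best-likelihood fit is kept and
`baseline_flag` is raised so downstream consumers can treat the sample as
needing review — flagged, never silently discarded.

### Segments and calls

Viterbi paths become segments; zero-inflation bins inherit the flanking
somy (larger side, ties left). Segments shorter than 10 Mb are reassigned
to their larger flank and re-merged iteratively, preserving a tiling of the
decoded territory (deleting them would leave chromosome calls without full
coverage). A chromosome's call is its bp-modal somy — ties break towards
3, then to the lower somy — classified as euploid (= 3), gain (> 3) or loss
(< 3); X is called exactly like an autosome, since all polar-body
chromatids are maternal. A sample is aneuploid with ≥ 1 aneuploid
chromosome and *highly complex* with more than half (≥ 12 of 23), the
regime where baseline shifts, rather than biology, usually dominate.
Chromosomes with no decoded bins propagate as `no-call`, never as euploid.

## The aCGH classifier

Expected log2 ratios follow directly from chromatid arithmetic:
$\log_2(4/3) = 0.42$ for a gain and $\log_2(2/3) = -0.58$ for a loss
against the 3-chromatid baseline (vs $0.58$ and $-1$ for diploid
material). Thresholds sit at the copy-number midpoints:
$\log_2(3.5/3) = 0.22$ for gains, $\log_2(2.5/3) = -0.26$ for losses.

An autosome is called aneuploid only when its mean log2 ratio crosses the
threshold **in both control channels** (male and female): the published
rule "above or below the defined thresholds (female and male)" is
ambiguous between both-channel and either-channel readings, and the
both-channel reading is adopted because a single-channel excursion is a
control-specific artifact. Chromosome X uses the female channel only — a
male control contributes one X against the sample's maternal chromatids.
Comparisons are strict; a mean exactly at a threshold stays euploid
(borderline profiles are review material, not silent calls).

The derivative log ratio spread, the standard aCGH noise metric, is
computed from within-chromosome successive probe differences with a robust
scale, $\mathrm{DLRS} = \mathrm{IQR}(d) / (1.349\sqrt{2})$, which equals
the per-probe noise SD under independent Gaussian noise; WGA outliers make
a raw SD unusable here.

## Concordance

`cross_table()` inner-joins two call sets at sample level
(euploid/aneuploid) or chromosome level (euploid/gain/loss, with every
somy below baseline mapped to "loss"). Per-class concordance conditions on
the method-A (aCGH) rows. `cohort_cross_tables()` ships the published
102-sample validation cohort tables; the handful of cells not printed
individually are solved from the published marginals, which leaves every
reported statistic unchanged. Denominators are always the package's own —
excluded units are listed, not silently dropped.

## The simulator and what it does (not) show

`simulate_reads()` draws read starts with probability proportional to
local chromatid count × GC bias × a per-window lognormal WGA factor, with
per-window dropout; `simulate_acgh()` places probes at the expected state
log2 plus Gaussian noise whose SD is the target DLRS. Defaults are the
study conditions: ~1 M reads per sample, DLRS 0.57, GC slope 0.8 per unit
GC deviation, lognormal log-SD 0.3 at 100-kb windows (≈ 10% bin-level
noise at 1 Mb), dropout probability 0.01. The synthetic layouts carry a
deterministic smooth GC track and a shared mappability landscape so GC
correction and variable-width binning are exercised against the artifacts
they exist for.

Desk-scale runs use a 1:30 genome (~103 Mb total) with the pipeline's
three length parameters — fixed bin, variable bin, minimal segment —
scaled by the same factor (`pipeline_config(scale = 30)`), preserving the
real bins-per-chromosome geometry: at 1 M reads both the full-size and the
scaled configuration put roughly 300 reads in each variable bin. The test
suite runs 50 such samples for end-to-end recovery and full-size genomes
for the segmental-detection and DLRS checks.

What passing simulations do **not** show: real WGA noise is heavier-tailed
and spatially structured beyond a lognormal per-window factor; real
mappability is sequence-driven rather than smooth; polar-body degradation
produces profile pathologies (partial amplification of one body) that no
parameter here reproduces. The simulator validates the *machinery* —
masking, binning, EM, anchoring, thresholds, bookkeeping — not the
biological error rates of any laboratory.

## Numerical choices and edge cases

* Coordinates are 0-based half-open internally; BED on output.
* Reads are represented by their start only (read length ≪ bin size) and
  duplicates are kept, matching the described workflow (no deduplication).
* Quantile masking uses strict inequalities, so a degenerate all-equal
  count distribution masks nothing.
* EM underflow is avoided by per-chromosome log-space forward–backward
  (C++); posteriors are renormalised row-wise.
* `fit_em(tol = Inf)` performs exactly one EM iteration — the stopping
  rule compares successive log-likelihoods.
* Downsampling uses seeded sampling without replacement and leaves the
  session RNG untouched (`withr::with_seed` everywhere randomness occurs).
* Chromosomes shorter than the minimal segment size keep their segments
  with a warning rather than failing.

## Limitations

Breakpoints are resolved only to bin boundaries; mosaicism is not
modelled (absent in polar bodies); embryo-level ploidy inference from
polar-body calls is out of scope, as is any clinical interpretation. The
anchoring loop is this package's mechanism for the modal-state constraint
and is surfaced as such via `baseline_flag`; samples where no 3-somy-modal
fit exists remain flagged rather than forced.
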