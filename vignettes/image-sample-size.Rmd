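---
title: "How many confocal images does a corneal immune-cell density estimate need?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many confocal images does a corneal immune-cell density estimate need?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdensity)
```

## The problem

In vivo confocal microscopy (IVCM) images a 400 μm × 400 μm field
(0.16 mm²) of corneal epithelium at a time. Epithelial immune-cell (IC)
density varies strongly from field to field, so an estimate built from a
handful of images can be far from the participant's underlying density.
Clinical studies have used anywhere from 3 to 12 images per participant,
often letting an observer hand-pick "representative" fields.

`icdensity` implements the subsampling analysis that answers two
questions about this practice:

1. **Sample size.** If a participant's *true mean* density is defined as
   the average over a 16-image non-overlapping reference set
   (2.56 mm² quantified area), how many randomly chosen images are
   needed so that the estimate is within 30% of the true mean, 95% of
   the time?
2. **Observer selection.** Are estimates from "three representative
   images" chosen by an observer consistent between observers, and more
   precise than three random images?

## The mean-ratio machinery

For a participant with image densities $d_1,\dots,d_n$ ($n = 16$) and
true mean $m = \bar d$, every unordered subset of $k$ images yields an
estimate $\bar d_S$ and a **mean ratio** $\bar d_S / m$. The package
enumerates all $\binom{n}{k}$ subsets exhaustively for $k = 2..15$ (at
most 12,870 per participant; Monte-Carlo subsampling is only a fallback
for larger designs and is off by default).

Two exact properties anchor the tests:

* **Symmetry.** Each image appears in $\binom{n-1}{k-1}$ subsets, so the
  enumerated ratios average to exactly 1.
* **Finite-population SD.** The subset mean drawn without replacement
  has variance $S^2 (1/k - 1/n)$, with $S^2$ the sample variance of the
  $n$ densities, so the ratio SD is $(S/m)\sqrt{1/k - 1/n}$
  (`exact_ratio_sd()`). Because the enumeration *is* the full population
  of estimates, the package summarises it with the population SD
  (divisor $N$), which matches this closed form to machine precision and
  makes `analytic_minimal_sample_size()` an independent, enumeration-free
  route to the same decision.

Ratios are pooled across participants at each $k$ (each participant
contributes the same number of combinations, and each participant's
distribution is centred at 1, so the pooled variance is the mean of the
per-participant variances). A per-participant breakdown is available from
`pooled_distribution()` for diagnostics.

## Tolerance bands and the decision rule

The pooled distribution at each $k$ is summarised by
$\mu \pm t \cdot SD$ at 80/85/90/95% confidence (`ratio_ci()`). Note the
band uses the **SD of the distribution of estimates**, not a standard
error: it is a tolerance band, which is exactly what "within 30% of the
true mean, 95% of the time" requires. The $t$ quantile uses $n - 1$
degrees of freedom on the pooled ratio count; with thousands of pooled
ratios this is numerically the normal quantile, but it keeps the printed
formula intact for small designs. The minimal sample size
(`minimal_sample_size()`) is the smallest $k$ whose band lies inside
$[1 - \delta,\, 1 + \delta]$, default $\delta = 0.30$ at 95%.

```{r kmin}
counts <- generate_counts(generator_config(seed = 20260925))
minimal_sample_size(ci_bands(counts, "central", levels = 0.95))
minimal_sample_size(ci_bands(counts, "peripheral", levels = 0.95))
```

Under the pure-Poisson generator at the published density summaries, the
central-region decision typically lands at 10–12 images and the
peripheral at 4–5. The real study reported 12 and 7: central agrees
well, while the peripheral gap is the expected signature of
overdispersion in real counts, which the generator's `dispersion` knob
can emulate but which the source data do not quantify (see *What the
generator does and does not emulate*).

## What the synthetic-data generator emulates

Raw per-image counts for the source study are not publicly available, so
every analysis here runs on seeded synthetic data built to the same
design:

* **Participant heterogeneity** — gamma with moments matched to the
  printed summaries (central 21.7 ± 17.7, peripheral 62.0 ± 26.1
  cells/mm²). Gamma rather than lognormal: positive support and
  closed-form moment matching, and only mean ± SD and range are
  published. Draws below 10⁻⁶ cells/mm² are redrawn so true means are
  never numerically zero (real low-density corneas could still produce
  all-zero image sets; the pipeline excludes such participant-regions
  from ratio analyses with a warning rather than failing).
* **Image-level counting noise** — Poisson with mean
  `density × 0.16 mm²` by default; a finite negative-binomial
  `dispersion` adds overdispersion. No dispersion estimate is published,
  so Poisson is the default and the knob is documented rather than
  calibrated.
* **Imperfect observers** — recounts are binomial thinning (per-cell
  detection probability) plus Poisson false positives. With detection
  0.95 and 0.2 spurious cells/image a 100-image, 3-observer panel gives
  an absolute-agreement ICC well above 0.9 (typically ~0.98, because the
  panel mixes low-density central and high-density peripheral images and
  the between-image variance dominates), emulating the reported
  "excellent agreement" regime. This is a tunable error mechanism, not a
  cognitive model.
* **Selection bias** — observers pick 3 images without replacement with
  weights $\propto \exp(\beta z)$, $z$ the within-participant
  standardised density ($z \equiv 0$ when the within-participant SD is
  0, making selection uniform). $\beta = 0$ is unbiased; $\beta \approx
  1$–2 emulates an observer drawn to cell-rich fields.
* Regions are generated independently; no inter-eye, age or dry-eye
  structure is modelled (none is reported).

Passing tests on these data demonstrate the *machinery* — enumeration,
bands, ICCs, test calibration — under the study's design. They cannot
certify the paper's specific 12/7 image numbers, which depend on the
unpublished within-participant variance structure.

## Agreement statistics

Both intraclass correlation forms are single-rating, two-way
random-effects, computed from the ANOVA mean squares of the complete
subjects × raters table (`anova_mean_squares()`):

* **Absolute agreement** (`icc_single_absolute()`):
  $(MS_S - MS_E) / (MS_S + (r-1)MS_E + \tfrac{r}{n}(MS_R - MS_E))$, used
  for the raw-count recounts; sensitive to systematic rater offsets. CI
  by the conventional F construction with Satterthwaite denominator df.
* **Consistency** (`icc_single_consistency()`):
  $(MS_S - MS_E) / (MS_S + (r-1)MS_E)$, used for the representative-image
  mean ratios; blind to constant per-rater shifts. CI from
  $F = MS_S / MS_E$ with $(n-1)$ and $(n-1)(r-1)$ df.

Negative estimates are reported as computed (the source study itself
reports −0.21). Missing cells are an error — the designs here are
complete, and imputation would silently change both forms. Simulated
coverage of the consistency CI at 20 subjects × 3 raters is ~95%
(checked in the test suite over 2000 tables).

## The representative-image comparison

Each observer's per-participant ratio (mean of the 3 selected densities
over the true mean) is compared against the exhaustive pool of all
$\binom{16}{3} = 560$ random 3-image subsets per participant:

* means by a pooled-variance Student's t-test (kept as the default
  despite the grossly unequal sizes, 20 vs 11,200, to match the printed
  procedure; Welch is available via `welch = TRUE`);
* variances by a two-sided F-test, $p = 2\min(P(F \le f), P(F \ge f))$;
* both Bonferroni-adjusted over the $m = 3$ raters within a region
  ($m$ is a parameter; whether the original family spanned both regions
  is not stated).

**Known limitation.** The t-test is well calibrated under unbiased
selection (empirical size ≈ 5% in both regions), but the F-test is not
robust in the central-region regime: with ~3.5 expected cells per image
and large participant heterogeneity, the 20 one-per-participant ratios
form a heavy-tailed, heteroscedastic mixture, and the two-sided F-test
over-rejects (~17% empirically, vs ~6% in the cell-rich peripheral
region where ratios are close to normal). This is the classical
non-normality fragility of variance F-tests, inherited from the printed
procedure; it is reported here rather than silently replaced by a robust
alternative.

## Numerical and design choices

* Enumeration order is the lexicographic order of index subsets
  (`utils::combn`), stable and documented; combination index matrices
  are cached per $(n, k)$.
* Binomial coefficients, subset means and the closed-form SD are exact
  in double precision at this design; the test suite asserts agreement
  between the enumeration and the closed form at $10^{-10}$.
* Degenerate inputs: constant densities give zero-width bands (every
  criterion satisfied at the smallest $k$ considered, $k = 2$);
  all-equal ratings make both ICCs undefined (error, not NaN); zero
  variance in either sample makes the t/F comparisons degenerate and
  flagged rather than computed.
* Seeds: every stochastic entry point either takes an explicit seed
  (`generate_counts()`, `simulate_selections()`,
  `simulate_recount_table()`) or documents that it consumes the current
  RNG state; seeded paths use `withr::with_seed`, so identical
  config + seed reproduces outputs byte-identically.
* Simulation sizes in the test suite (1000 null replicates for test
  calibration, 2000 tables for CI coverage, 100 datasets for the
  decision-agreement check) were chosen to keep Monte-Carlo error well
  inside the asserted bounds while remaining desk-scale.

## Reading the outputs

The `analysis/` scripts run the full pipeline on one seeded dataset and
write per-region band tables (`bands_<region>.csv`), sample-size
decisions (`sample_size_<region>.json`), observer-comparison reports
(`comparison_<region>.json`) and the associated figures under
`results/`; every run writes a provenance JSON (config, seed, package
version) sufficient to regenerate it. The figures are regenerable from
the CSV/JSON outputs alone.
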