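# icdensity

How many non-overlapping in vivo confocal microscopy (IVCM) images are
needed to estimate corneal epithelial immune-cell (IC) density reliably?
`icdensity` implements the subsampling analysis behind that question for
researchers planning or auditing IVCM imaging protocols: it enumerates
k-image subsets of a participant's 16-image reference set, determines the
minimal sample size meeting a stated precision, quantifies inter-observer
agreement with intraclass correlation coefficients, and evaluates the
common "three representative images" practice against random image
selection. Because the underlying per-image counts of the source study
are not publicly available, a seeded synthetic-data generator reproduces
the study design so the whole pipeline is runnable and testable end to
end.

## The statistics

For a participant with per-image densities d₁,…,dₙ (n = 16 images of
0.16 mm², 2.56 mm² total) the *true mean* is m = d̄. Every unordered
k-subset S gives an estimate d̄_S and a **mean ratio** d̄_S / m. The
package enumerates all C(n, k) subsets exhaustively for k = 2..15 and
summarises the pooled ratios with tolerance bands

    CI = μ ± t · SD

at 80/85/90/95% confidence, where SD is the standard deviation of the
ratio *distribution* (so the band contains the stated fraction of
estimates). The minimal sample size k_min is the smallest k whose 95%
band lies within [1 − δ, 1 + δ], default δ = 0.30. Two exact identities
back the enumeration: the ratios average to exactly 1, and their SD
equals the finite-population form (S/m)·√(1/k − 1/n), which yields an
independent closed-form route to the same k_min decision
(`analytic_minimal_sample_size()`).

Agreement statistics are single-rating two-way random-effects ICCs from
ANOVA mean squares — absolute agreement for raw recounts, consistency for
the representative-image ratios — with F-based confidence intervals. The
observer evaluation compares each (simulated) observer's 3-image
estimates against the exhaustive pool of all 560 random 3-image subsets
per participant: Student's t for means, a two-sided F-test for
variances, Bonferroni-adjusted over the raters.

## Worked example

The `analysis/` scripts run the whole pipeline on one seeded dataset and
write tables/figures under `results/`:

```sh
Rscript analysis/01_simulate.R       # synthetic study dataset + provenance
Rscript analysis/02_sample_size.R    # bands, k_min per region, figures
Rscript analysis/03_agreement.R      # inter-observer recount ICC
Rscript analysis/04_observer_bias.R  # representative-image evaluation
```

`02_sample_size.R` prints, for the default seed:

```
central: k_min = 13 (closed-form check: 13)
peripheral: k_min = 4 (closed-form check: 4)
```

meaning 13 random central-cornea images (4 peripheral) keep the density
estimate within 30% of the participant's true mean 95% of the time for
this dataset; enumeration and the closed form agree. In R, the same
result from scratch:

```r
library(icdensity)
counts <- generate_counts(generator_config(seed = 20260925))
minimal_sample_size(ci_bands(counts, "central", levels = 0.95))
#> <ic_sample_size>
#>   region: central, criterion: within 30% of true mean, 95% of the time
#>   k_min: 13
```

`04_observer_bias.R` contrasts unbiased simulated observers (β = 0) with
observers drawn to cell-rich fields (β = 1). At β = 1 every rater's mean
ratio is inflated (central ≈ 1.5–1.8, t-test p ≪ 0.01 against the
random-subset pool), while inter-observer consistency of the ratios
stays far below the "good" range in the peripheral region — the
signature of the representative-image method's bias and unreliability.

Across seeds, the pure-Poisson generator puts the central k_min near the
12 reported by the source study, while the peripheral k_min (typically
4–5) falls below the reported 7 — consistent with real peripheral counts
being overdispersed relative to Poisson (the generator's `dispersion`
knob exposes this; no published estimate exists to calibrate it).

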