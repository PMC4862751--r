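---
title: "Detecting 24-hour transcript cycling and its genotype-specific loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 24-hour transcript cycling and its genotype-specific loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmscan)
```

## The problem

Circadian transcriptome experiments collect a tissue (liver, fat body)
every few hours across one day in a small number of animals, and ask which
transcripts oscillate with a ~24-h period — and, when two genotypes are
profiled in parallel, which transcripts *lose* their oscillation in one of
them. The designs are short and replicated rather than long and dense: the
canonical layout here is 6 timepoints every 4 h starting at lights-on
(ZT0), with 2 replicates per genotype and timepoint for arrays and 3–4 for
qPCR. No single test is well powered for every waveform at these sizes, so
the pipeline combines two complementary detectors and integrates their
p-values.

## Rhythm detection

### Rank test against cosine references (JTK_CYCLE)

`jtk_test()` correlates the observed series with cosine reference
waveforms `cos(2*pi*(t - lag)/period)` peaking at each lag on a grid, via
the Kendall score

\[ S = \sum_{i<j} \mathrm{sign}\big((x_i - x_j)(r_i - r_j)\big), \]

where pairs tied in either vector contribute 0. Because replicates share a
collection time — and times symmetric about the reference peak share a
cosine value — the reference contains ties by construction, and the null
distribution of `S` under random ranking of the data is computed
**exactly** for that tie pattern by convolving Gaussian binomial
coefficients (`jtk_null()`). Lags half a period apart have negated
references and identical `|S|`, so they are collapsed into one
alternative; the reported p-value is the Bonferroni-adjusted minimum
two-sided tail probability over the distinct lag groups (3 groups for a
24-h period scanned at the 4-h sampling interval). The test is
distribution-free: any strictly monotone transform of the data leaves `p`
and the best lag unchanged. Data ties (exactly equal expression values)
contribute 0 to `S` but are ignored in the null — the standard
approximation, harmless for continuous expression values.

Design choices worth knowing:

* **Period fixed at 24 h.** The experiments are one-day entrained
  collections; scanning periods is possible (`period_h` is a parameter)
  but off by default, and the Bonferroni count then reflects the larger
  alternative set.
* **Lag grid at the sampling interval.** With 4-h sampling there is no
  rank information between grid lags, so a finer grid only inflates the
  alternative count. Finer phase estimates come from the harmonic fit and
  the phase integration below.
* **Replicates as ties, not averages.** Averaging replicates would
  discard the within-timepoint ordering information the exact null
  accounts for.

### Lomb–Scargle periodogram

`ls_power()` computes the mean-subtracted, variance-normalized
Lomb–Scargle power `z` at the single target frequency `1/period`, in the
tau-offset form (invariant to the time origin; replicates enter as
repeated observations). `ls_test()` converts it with the Scargle
false-alarm law `p = 1 - (1 - e^{-z})^M`. With the period fixed in
advance the effective number of independent frequencies is `M = 1`
(`p = e^{-z}`); a scan over k frequencies should set `M = k` explicitly.

The exponential law is asymptotic in the sample count. On the replicated
designs where the tests are routinely applied (18–24 samples) it is
accurate — on the 6×4 h×4 replicate design, 2000 white-noise simulations
give a Kolmogorov–Smirnov distance of ~0.026 from uniform (p = 0.13). On
the smallest 12-sample design the finite-sample null (a Beta-type law
with survival \((1 - 2z/(N-1))^{(N-3)/2}\)) deviates more: the
exponential approximation is slightly anti-conservative in the mid-range
of p and conservative in the far tail that significance calls actually
use. This is a documented limitation, not corrected silently, because the
simple exponential form is the convention the integrated pipeline is
calibrated against.

### Fisher integration and its caveat

`fisher_combine()` integrates the per-method p-values with Fisher's
method: \(X = -2\sum \ln p_i \sim \chi^2_{2k}\) under independence.
The two detectors are computed on the *same* series and are strongly
positively correlated (Spearman ~0.85 on white noise), so the integrated
p-value is approximate: in 5000 null simulations on the 12-sample design
the integrated test rejects ~2.2% at a nominal 1%. The rank test alone is
conservative (4.6% at a nominal 5%). Fisher is used deliberately —
it is the field's standard integration for this pipeline — and the
inflation is stated rather than patched; a dependence-adjusted
combination (Brown's method) would trade transparency for calibration and
is out of scope.

## Per-transcript features

* **Harmonic fit.** `harmonic_fit()` is ordinary least squares of
  `y = b + alpha*cos(wt) + beta*sin(wt)` at the fixed period; amplitude
  `A = sqrt(alpha^2 + beta^2)`, peak phase `phi = atan2(beta, alpha)/w`
  mapped to `[0, 24)`. Noiseless cosines are recovered exactly; the fit
  is the amplitude/phase estimator because the detectors themselves
  return only a coarse lag (rank test) or a power (periodogram).
* **bEXP** (`compute_bexp()`): the arithmetic mean of all sample values
  collected within one period length — the baseline expression level on
  the linear scale. On an even full-period grid the cosine component
  averages out exactly, so bEXP estimates the true baseline without
  waveform bias.
* **rAMP** (`compute_ramp()`): amplitude normalized by bEXP,
  dimensionless and invariant to rescaling the series. The plain
  `amplitude/bEXP` normalization is the default; the sample median
  (`median_exp`) is reported in a separate column rather than replacing
  the mean in bEXP.
* **Integrated phase** (`integrate_phase()`): the amplitude-weighted
  circular mean of the method phases (the rank test's best lag and the
  periodogram's fitted phase). The rank test carries no amplitude of its
  own, so the harmonic-fit amplitude weights its lag. The circular mean
  handles the midnight wrap (23 h and 1 h average to 0 h). The weighting
  is configurable (`phase_method` = `"weighted"`, `"harmonic"`, `"jtk"`,
  `"ls"`) because the best convention is genuinely open; the weighted
  default degrades gracefully when one method's phase is missing.

`analyze_matrix()` applies all of the above per transcript and group,
never aborting on a degenerate transcript: constant series get `p = 1`
(`flag = "constant"`), series with fewer than 4 distinct timepoints after
removing missing values are flagged `insufficient_data`, and any other
per-transcript error is captured in the `flag` column.

## Differential cycling

`classify_cycling()` applies the stringent two-threshold convention:
a transcript is **WT-specific** when it is expressed, cyclic in WT
(integrated `p < 0.01`) and non-cyclic in KO (`p > 0.8`); symmetrically
for KO-specific; transcripts cyclic in both at the looser `p < 0.05` are
**common** and receive a signed circular phase delay
`((phi_KO - phi_WT + 12) mod 24) - 12`; the rest are **neither** or
**not expressed**. The labels partition the transcript universe. The
expressed filter (`bEXP > 101.6`, strict) is applied before all
classifications; 101.6 is the linear-scale threshold separating expressed
from background probes on the arrays this pipeline targets, and it is a
plain parameter everywhere. A transcript counts as expressed if it passes
in either genotype, so a transcript silenced in one genotype is not
discarded by the very comparison that should flag it.

Two properties of this rule deserve emphasis, because they bound what any
user should expect from it:

* **It is precise, not sensitive.** The `p > 0.8` arm asks a *null*
  series to look emphatically null. Under the integrated test the
  probability that a truly non-cycling series exceeds 0.8 is only ~0.44
  (and at most ~0.56 even if the rank test always returned 1), so no more
  than about half of the transcripts that genuinely lose cycling can ever
  be labelled WT-specific — independent of amplitude or noise level. In
  the synthetic end-to-end experiment the rule recovers ~40–45% of
  planted WT-only cyclers at ~94–97% precision. The rule buys a clean
  list, not a complete one.
* **Threshold presets are conventions.** The stringent pair
  (0.01, 0.8) is one published convention; per-gene tables in the
  literature often reflect looser criteria. All four thresholds are
  explicit parameters.

`venn_counts()` reports the loose-threshold overlap; `phase_delay()`
summarizes the signed delays of common cyclers with the median and a
two-sided sign test; `heatmap_prepare()` builds the display matrix the
way such heatmaps are conventionally drawn: replicates averaged per
timepoint, each row divided by its median (rows with non-positive median
are dropped and reported), rows sorted by phase.

## The synthetic-data generator

`generate_experiment()` produces paired WT/KO matrices with ground truth.
The signal model is a single cosine at exactly 24 h,

\[ y(t) = \big[b + A\cos(2\pi(t-\varphi)/24)\big]\,\varepsilon_{mult} + \varepsilon_{add}, \]

with mean-1 lognormal multiplicative noise (default sdlog 0.1) and
additive Gaussian noise (default sd 1). Defaults encode the study
conditions the pipeline targets: the 6×4 h×2 replicate design per
genotype; baselines log-uniform on [20, 2000] so the expressed filter at
101.6 genuinely bisects the population; phases uniform on [0, 24);
relative amplitudes of cyclers uniform on [0.2, 0.8] — no empirical
effect-size distribution is available for calibration, so the range was
chosen once to span weak-but-detectable (power is moderate at A/b = 0.3
with 2 replicates) through robust cycling; 30% WT-only cyclers, 30%
common cyclers with a +2 h KO phase delay, the rest flat. Positivity is
enforced by requiring `b - A > 3 * sd_add`. Output is a deterministic
function of the seed.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: probe-level microarray noise and
cross-hybridization, batch and array effects, non-sinusoidal waveforms
(sawtooth transcripts, damped oscillations), heteroskedasticity beyond
the multiplicative term, and correlated transcripts. Recovery rates on
synthetic data are best-case figures for the statistical machinery, not
forecasts for any particular array platform.

## Numerical choices and degenerate inputs

* The exact-null convolution uses double-precision counts; for the
  largest supported designs (~28 samples) the multinomial totals exceed
  2^53, so pmf entries are exact to relative ~1e-16 rather than exact
  integers — far below any p-value tolerance that matters. The pmf is
  validated against brute-force enumeration for every design size where
  enumeration is feasible (n ≤ 8).
* Reference values are rounded to 9 decimals before tie-grouping, so
  floating-point fuzz cannot split a tie group.
* Ties in the best-lag selection are broken toward the smaller lag, then
  the larger `|S|`; antiphase lags report the lag of the *positive*
  correlation (`lag + 12` when `S < 0`).
* p-values of exactly 0 from an upstream test are clamped to the smallest
  positive double before the Fisher log.
* Zero-variance series: the periodogram reports power 0 and p 1 with a
  degenerate flag; the rank test reports p 1, tau 0.
* Phases of effectively amplitude-free fits are `NA`, never 0, so a flat
  transcript cannot masquerade as a ZT0 peaker.

## Problem sizes used in validation

The shipped validation uses 1000-transcript experiments (12 s per
genotype pair on one CPU), 500-simulation recovery grids, 2000-simulation
null calibrations, and exhaustive permutation oracles up to n = 8
(40,320 permutations). These sizes give Monte-Carlo error comfortably
below the asserted tolerances (e.g. binomial sd ~0.005 on a 5% rejection
rate at 2000 simulations) while keeping the whole suite under two
minutes.

## Known limitations

* Fisher integration is anti-conservative under method dependence (see
  above); treat integrated p-values near a threshold accordingly.
* The exponential periodogram law is approximate at 12 samples.
* The rank test's phase resolution is the lag grid; sub-interval phase
  information comes entirely from the harmonic fit.
* The WT-specific rule's sensitivity is structurally capped near 50%
  (see above); comparisons of *counts* of genotype-specific cyclers
  between studies using different thresholds are not meaningful.
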