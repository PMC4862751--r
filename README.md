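# rhythmscan

Detection of 24-hour transcript cycling — and of its genotype-specific
loss — in short, replicated expression time courses.

Circadian experiments profile a tissue every few hours over one day
(typically 6 timepoints × 4 h, 2–4 replicates each) in two genotypes, and
ask two questions: *which transcripts oscillate?* and *which transcripts
stop oscillating when a gene (e.g. a neuropeptide) is knocked out?*
`rhythmscan` answers both with the standard two-detector integration used
for such designs, plus a ground-truth simulator so every stage is
testable without any external data. It is aimed at researchers analyzing
array/qPCR-style circadian time courses and at methodologists who want
calibrated, exactly-specified building blocks.

## Statistical core

For a series `x(t)` and a fixed target period `T = 24 h`:

* **Rank test (JTK_CYCLE).** Kendall score against cosine references
  peaking at each lag, `S = Σ_{i<j} sign((x_i − x_j)(r_i − r_j))`, with
  an **exact** permutation null for the tie pattern the replicated design
  induces in the reference (Harding-style convolution of Gaussian
  binomial coefficients). Antiphase lags are collapsed via `|S|` and the
  minimum two-sided tail probability is Bonferroni-adjusted over the lag
  groups. Distribution-free: invariant under monotone transforms.
* **Lomb–Scargle periodogram.** Variance-normalized power `z` at `1/T`
  in the tau-offset form; significance `p = 1 − (1 − e^{−z})^M`, `M = 1`
  for the single pre-specified period.
* **Fisher integration.** `X = −2(ln p_JTK + ln p_LS) ~ χ²₄`.
* **Features.** Single-harmonic OLS fit for amplitude and phase;
  baseline expression `bEXP` = mean over one period; relative amplitude
  `rAMP = amplitude / bEXP`; amplitude-weighted circular mean phase.
* **Differential cycling.** A transcript is *WT-specific* when expressed
  (`bEXP > 101.6`), cyclic in WT (`p < 0.01`) and non-cyclic in KO
  (`p > 0.8`); *common* cyclers (`p < 0.05` in both) get a signed
  circular phase delay in `(−12, 12]`.

See `vignettes/rhythmscan-methods.Rmd` for the model, the calibration
measurements and the known limitations (notably: Fisher integration is
mildly anti-conservative because the two detectors are correlated, and
the `p > 0.8` arm structurally caps the sensitivity of the WT-specific
rule near 50% — it yields a precise list, not a complete one).

## Worked example

```r
library(rhythmscan)

design <- sim_design()                      # 6 timepoints x 4 h x 2 reps
y <- generate_transcript(design, baseline = 155.9, amplitude = 135,
                         phase_h = 17.75, seed = 101)
round(y, 1)
#>  [1] 143.1 153.2  32.2  35.2  44.0  48.9 173.6 160.0 301.9 270.2 281.0 245.0

res <- rhythmscan:::analyze_series(y, design)
sprintf("p_jtk = %.3g  p_ls = %.3g  integrated p = %.3g",
        res$p_jtk, res$p_ls, res$p_value)
#> "p_jtk = 0.000115  p_ls = 0.00439  integrated p = 7.85e-06"
sprintf("phase = %.2f h  bEXP = %.1f  rAMP = %.3f  median = %.1f",
        res$phase_h, res$bexp, res$ramp, res$median_exp)
#> "phase = 16.83 h  bEXP = 157.3  rAMP = 0.864  median = 156.6"
```

The rank test alone reaches `p = 1.15e-04` (three lag groups × the exact
tail at `|S| = 50`), the periodogram contributes `p = 4.4e-03`, and
Fisher integration combines them. The fitted peak at ZT16.8 sits within
one sampling interval of the planted ZT17.75 phase; `rAMP = 0.864` means
the oscillation's amplitude is 86% of the baseline — a robust cycler.

The same functions operate on whole matrices: the numbered drivers under
`analysis/` run the full workflow (simulate → detect → compare) and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect_rhythms.R
Rscript analysis/03_differential_cycling.R
```

which, with the shipped defaults (1000 transcripts: 300 WT-only cyclers,
300 common cyclers with a +2 h KO delay, 400 flat), prints among other
things:

```
Classification (expressed filter bEXP > 101.6):
not_expressed   wt_specific   ko_specific        common       neither
          324            94             3           208           371
Venn at p < 0.05: 425 cyclic in WT, 228 in KO, 208 common
Common cyclers: median KO-WT phase delay 1.34 h (sign test p = 1.5e-50, n = 208)
WT-specific call vs truth: sensitivity 0.30, precision 0.97
```

Real data enter through `read_expression_matrix(matrix, design)` — a
delimited table of transcripts × samples plus a design table
(`sample_id`, `time_h`, `replicate`, `group`); use `delog2 = TRUE` for
log2 input, since all thresholds are defined on the linear scale.

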