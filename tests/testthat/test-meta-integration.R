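# Fisher combination, harmonic fit, bEXP/rAMP, phase integration,
# whole-matrix analysis.

test_that("Fisher combination matches its chi-square closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  # X = -2*ln(0.25) = 2.7726; df 4 survival is exp(-X/2)*(1 + X/2)
  X <- -2 * log(0.25)
  expect_equal(fisher_combine(c(0.5, 0.5)), exp(-X / 2) * (1 + X / 2))
  expect_equal(round(fisher_combine(c(0.5, 0.5)), 4), 0.5966)
  # identity on a single input
  set.seed(2)
  for (p in runif(10)) expect_equal(fisher_combine(p), p)
})

test_that("combined p is strictly increasing in each input", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(2, 0.01, 0.95)
    eps <- 0.02
    expect_lt(fisher_combine(p), fisher_combine(p + c(eps, 0)))
    expect_lt(fisher_combine(p), fisher_combine(p + c(0, eps)))
  }
  expect_error(fisher_combine(c(0, 0.5)), "clamp_zero")
  expect_gt(fisher_combine(c(0, 0.5), clamp_zero = TRUE), 0)
  expect_error(fisher_combine(numeric(0)))
})

test_that("harmonic fit recovers noiseless parameters exactly", {
  d <- sim_design()
  fit <- harmonic_fit(cosine_series(d, 100, 50, 16), d)
  expect_equal(fit$baseline, 100)
  expect_equal(fit$amplitude, 50)
  expect_equal(fit$phase_h, 16)
  flat <- harmonic_fit(rep(100, 12), d)
  expect_equal(flat$baseline, 100)
  expect_equal(flat$amplitude, 0)
  expect_true(flat$degenerate && is.na(flat$phase_h))
  d2 <- time_design(c("a", "b", "c", "d"), c(0, 0, 12, 12),
                    c(1, 2, 1, 2), "WT")
  expect_error(harmonic_fit(c(1, 2, 3, 4), d2), "distinct")
})

test_that("amplitude estimates are unbiased to within 5% under noise", {
  d <- sim_design()
  set.seed(21)
  A <- 60
  ahat <- replicate(500, {
    y <- generate_transcript(d, 200, A, 10, sigma_mult = 0.1, sd_add = 1)
    harmonic_fit(y, d)$amplitude
  })
  expect_lt(abs(mean(ahat) - A) / A, 0.05)
})

test_that("bEXP is the mean over one period and rAMP its normalization", {
  d <- sim_design()
  expect_equal(compute_bexp(rep(100, 12), d), 100)
  # even full-period grid: the cosine sums to zero, mean is the baseline
  expect_equal(compute_bexp(cosine_series(d, 100, 50, 7), d), 100)
  # two values at one timepoint average plainly; samples outside the
  # period window are ignored
  d1 <- time_design(c("a", "b", "c"), c(0, 0, 25), c(1, 2, 1), "WT")
  expect_equal(compute_bexp(c(50, 150, 1e6), d1, 24), 100)
  late <- time_design(c("a", "b", "c"), c(30, 40, 50), 1:3, "WT")
  expect_error(compute_bexp(1:3, late, 24), "within one period")
  expect_equal(compute_ramp(50, 100), 0.5)
  expect_equal(compute_ramp(0, 100), 0)
  expect_error(compute_ramp(10, 0), "bexp")
})

test_that("rAMP is scale-invariant while bEXP scales with the series", {
  d <- sim_design()
  y <- generate_transcript(d, 150, 60, 3, seed = 14)
  r1 <- rhythmscan:::analyze_series(y, d)
  r2 <- rhythmscan:::analyze_series(10 * y, d)
  expect_equal(r2$ramp, r1$ramp)
  expect_equal(r2$bexp, 10 * r1$bexp)
})

test_that("circular phase integration averages across the wrap", {
  expect_equal(integrate_phase(c(16, 16), c(1, 1)), 16)
  expect_equal(circ_dist(integrate_phase(c(23, 1), c(1, 1)), 0), 0,
               tolerance = 1e-9)
  expect_equal(integrate_phase(c(8, 20), c(1, 0)), 8)
  # antipodal equal weights: resultant vector vanishes
  expect_true(is.na(integrate_phase(c(2, 14), c(1, 1))))
})

test_that("matrix analysis is complete, deterministic and row-independent", {
  ex <- generate_experiment(n_transcripts = 30, frac_wt_only = 0.5,
                            seed = 17)
  res <- analyze_matrix(ex$wt)
  expect_equal(nrow(res), 30L)
  ok <- res$flag == "ok"
  expect_true(all(ok))
  num <- c("p_jtk", "p_ls", "p_value", "phase_h", "amplitude", "bexp",
           "ramp", "median_exp")
  expect_true(all(is.finite(as.matrix(res[ok, num]))))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$phase_h >= 0 & res$phase_h < 24))
  # permuting transcript rows permutes results identically
  perm <- sample(nrow(ex$wt$values))
  em2 <- expression_matrix(ex$wt$values[perm, ], ex$wt$design)
  res2 <- analyze_matrix(em2)
  expect_equal(res2[order(res2$transcript_id), ],
               res[order(res$transcript_id), ], ignore_attr = TRUE)
  # median_exp is the plain sample median
  expect_equal(res$median_exp[1], median(ex$wt$values[1, ]))
})

test_that("missing data are analyzed when enough timepoints remain", {
  ex <- generate_experiment(n_transcripts = 2, frac_wt_only = 1,
                            frac_common = 0, seed = 23)
  vals <- ex$wt$values
  vals[1, 1:2] <- NA            # drops one timepoint, 5 remain
  vals[2, 1:6] <- NA            # only 3 distinct timepoints remain
  res <- analyze_matrix(expression_matrix(vals, ex$wt$design))
  expect_equal(res$flag, c("ok", "insufficient_data"))
  expect_true(is.finite(res$p_value[1]))
  expect_true(is.na(res$p_value[2]))
})

test_that("constant transcripts are flagged with p = 1 rather than dropped", {
  d <- sim_design()
  m <- rbind(g1 = rep(100, 12),
             g2 = generate_transcript(d, 100, 40, 6, seed = 3))
  colnames(m) <- d$sample_id
  res <- analyze_matrix(expression_matrix(m, d))
  expect_equal(res$flag, c("constant", "ok"))
  expect_equal(res$p_value[1], 1)
  expect_equal(res$ramp[1], 0)
})
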