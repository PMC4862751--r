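# Rank test: reference construction, Kendall score, exact null, full test.

test_that("cosine references have the expected values and tie structure", {
  d1 <- sim_design(n_reps = 1)
  expect_equal(jtk_reference(24, 0, d1), c(1, 0.5, -0.5, -1, -0.5, 0.5))
  # lag 12 negates lag 0 on the same grid
  expect_equal(jtk_reference(24, 12, d1), -jtk_reference(24, 0, d1))
  # replicates share reference values: 6 distinct among 12 samples
  d2 <- sim_design(n_reps = 2)
  expect_equal(length(unique(jtk_reference(24, 1, d2))), 6L)
  expect_error(jtk_reference(-24, 0, d1), "period")
  expect_error(jtk_reference(24, 25, d1), "lag")
})

test_that("Kendall score matches hand-enumerated pairs", {
  expect_equal(kendall_s(1:4, 1:4)[c("S", "tau")], list(S = 6L, tau = 1))
  expect_equal(kendall_s(4:1, 1:4)[c("S", "tau")], list(S = -6L, tau = -1))
  expect_equal(kendall_s(c(1, 3, 2, 4), 1:4)$S, 4L)  # 5 concordant, 1 discordant
  # pairs tied in either vector contribute zero
  expect_equal(kendall_s(c(1, 1, 2, 3), c(1, 2, 2, 3))$S, 4L)
  deg <- kendall_s(rep(5, 6), 1:6)
  expect_true(deg$degenerate)
  expect_equal(deg$S, 0L)
  expect_equal(deg$tau, 0)
})

test_that("exact null for three untied observations matches 3! enumeration", {
  null <- jtk_null(c(1, 1, 1))
  expect_equal(null$S, c(-3, -1, 1, 3))
  expect_equal(null$prob, c(1, 2, 2, 1) / 6)
})

test_that("exact null equals brute-force permutation enumeration", {
  # all design sizes <= 8, with and without reference ties
  for (sizes in list(c(1, 1, 1, 1), c(2, 2, 2), c(2, 3, 2), c(4, 4),
                     c(1, 2, 3), c(2, 2, 2, 2))) {
    null <- jtk_null(sizes)
    bf <- brute_force_null(sizes)
    merged <- merge(null, bf, by = "S", all = TRUE)
    merged[is.na(merged)] <- 0
    expect_equal(merged$prob.x, merged$prob.y, tolerance = 1e-12,
                 label = paste("pmf for sizes", paste(sizes, collapse = ",")))
  }
})

test_that("null pmf is symmetric, sums to one, and has bounded support", {
  for (sizes in list(c(2, 4, 4, 2), c(3, 3, 3, 3), c(1, 1, 5), c(4, 4, 4))) {
    null <- jtk_null(sizes)
    expect_equal(sum(null$prob), 1, tolerance = 1e-12)
    expect_equal(null$prob, rev(null$prob))  # P(S=s) = P(S=-s)
    M <- (sum(sizes)^2 - sum(sizes^2)) / 2   # untied pair count
    expect_equal(range(null$S), c(-M, M))
  }
  expect_error(jtk_null(c(1, 1)), "at least 3")
})

test_that("noiseless cosine attains the minimum achievable adjusted p", {
  d <- sim_design()  # 6 timepoints x 2 reps
  y <- cosine_series(d, b = 100, A = 50, phase = 16)
  res <- jtk_test(y, d)
  expect_equal(res$best_lag_h, 16)
  expect_equal(res$tau, 1)
  expect_equal(res$n_alternatives, 3L)
  # reference tie groups at any 4h lag are {2,4,4,2}; the number of
  # distinct orderings is the multinomial 12!/(2!4!4!2!) = 207900, the
  # two extreme orderings are +-S_max, and 3 antiphase-paired lag groups
  # are Bonferroni-counted
  n_orderings <- factorial(12) / (factorial(2)^2 * factorial(4)^2)
  expect_equal(res$p_value, 3 * 2 / n_orderings)
})

test_that("constant series carry no concordance information", {
  d <- sim_design()
  res <- jtk_test(rep(7, 12), d)
  expect_equal(res$p_value, 1)
  expect_equal(res$tau, 0)
  expect_true(res$degenerate)
})

test_that("p and lag are invariant under strictly monotone transforms", {
  d <- sim_design()
  set.seed(31)
  for (i in 1:20) {
    x <- generate_transcript(d, 200, sample(c(0, 80), 1), runif(1, 0, 24))
    base <- jtk_test(x, d)
    for (f in list(function(v) exp(v / 100), function(v) v^3,
                   function(v) 5 * v - 3, function(v) rank(v))) {
      tr <- jtk_test(f(x), d)
      expect_equal(tr$p_value, base$p_value)
      expect_equal(tr$best_lag_h, base$best_lag_h)
    }
  }
})

test_that("adjusted p equals enumeration over all rank permutations (n=8)", {
  # oracle equivalence on a small design: one-day sampling, 4 timepoints
  # x 2 reps, so every rank permutation can be scored directly
  d <- time_design(sprintf("s%d", 1:8), rep(c(0, 6, 12, 18), each = 2),
                   rep(1:2, 4), "WT")
  lags <- c(0, 6)  # antiphase partners 12 and 18 collapse onto these
  perms <- perm_matrix(8)
  pairs <- which(upper.tri(diag(8)), arr.ind = TRUE)
  refs <- lapply(lags, function(l) cos(2 * pi * (d$time_h - l) / 24))
  # S over every rank permutation at once, one reference at a time
  S_all <- function(ref) {
    rs <- sign(round(ref[pairs[, 2]] - ref[pairs[, 1]], 9))
    s <- numeric(nrow(perms))
    for (k in which(rs != 0)) {
      s <- s + rs[k] * sign(perms[, pairs[k, 2]] - perms[, pairs[k, 1]])
    }
    s
  }
  set.seed(4)
  for (rep in 1:3) {
    x <- rnorm(8)
    per_lag <- sapply(seq_along(refs), function(i) {
      s_obs <- kendall_s(x, refs[[i]])$S
      if (s_obs == 0) 1 else mean(abs(S_all(refs[[i]])) >= abs(s_obs))
    })
    expect_equal(jtk_test(x, d, lag_step_h = 6)$p_value,
                 min(1, length(lags) * min(per_lag)))
  }
})

test_that("the test is conservative on white-noise nulls", {
  d <- sim_design()
  set.seed(12)
  p <- replicate(1000, jtk_test(rnorm(12), d)$p_value)
  mc <- 2 * sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(p <= 0.05), 0.05 + mc)
})
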