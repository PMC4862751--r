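# Rank-based rhythmicity test (JTK_CYCLE): Kendall correlation of a series
# against time-shifted cosine references at a fixed period, with an exact
# permutation null that accounts for the tie structure the replicated
# design induces in the reference.

#' Cosine reference waveform for the rank test
#'
#' One reference value `cos(2*pi*(t - lag_h)/period_h)` per sample.
#' Replicates collected at the same time share a reference value, so the
#' reference carries ties by construction; so do times symmetric about the
#' peak (e.g. ZT4 and ZT20 for a lag-0, 24-h reference).
#'
#' @param period_h target period, hours (> 0).
#' @param lag_h reference peak time, hours, in `[0, period_h)`.
#' @param design a [time_design()].
#' @return Numeric vector, one value per design sample.
#' @examples
#' d <- sim_design(n_reps = 1)
#' jtk_reference(24, 0, d)  # 1, 0.5, -0.5, -1, -0.5, 0.5
#' @export
jtk_reference <- function(period_h, lag_h, design) {
  if (!is.numeric(period_h) || period_h <= 0) stop("period_h must be > 0")
  if (lag_h < 0 || lag_h >= period_h) stop("lag_h must be in [0, period_h)")
  cos(2 * pi * (design$time_h - lag_h) / period_h)
}

#' Kendall score of a series against a reference
#'
#' `S = sum over pairs i<j of sign((x_i - x_j)(ref_i - ref_j))`; pairs tied
#' in either vector contribute 0.  `tau` is the tie-corrected normalization
#' `S / sqrt((n0 - n_tx)(n0 - n_tr))` with `n0 = n(n-1)/2` and `n_tx`,
#' `n_tr` the tied pair counts of `x` and `ref`.
#'
#' @param x numeric series values.
#' @param ref numeric reference vector of equal length.
#' @return List with `S` (integer score), `tau`, and `degenerate` (`TRUE`
#'   when all `x` are tied, in which case `S = 0`, `tau = 0`).
#' @export
kendall_s <- function(x, ref) {
  n <- length(x)
  if (length(ref) != n) stop("x and ref must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  if (any(!is.finite(x)) || any(!is.finite(ref))) {
    stop("x and ref must be finite")
  }
  # round the reference so floating-point fuzz cannot split a tie group
  # (e.g. cos(pi/3) vs cos(-pi/3)); ties must compare exactly equal
  ref <- round(ref, 9)
  dx <- sign(outer(x, x, "-"))
  dr <- sign(outer(ref, ref, "-"))
  S <- sum((dx * dr)[lower.tri(dx)])
  n0 <- n * (n - 1) / 2
  tied_pairs <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  ntx <- tied_pairs(x)
  ntr <- tied_pairs(ref)
  degenerate <- ntx == n0
  denom <- sqrt((n0 - ntx) * (n0 - ntr))
  tau <- if (degenerate || denom == 0) 0 else S / denom
  list(S = as.integer(round(S)), tau = tau, degenerate = degenerate)
}

# Gaussian binomial coefficients [m+s choose s]_q as a double vector of
# length m*s + 1: coefficient i+1 counts the interleavings of s new items
# into m old items with exactly i "inversions".  Built by the product
# formula prod_k (1 - q^(m+k)) / (1 - q^k); both steps are exact integer
# polynomial operations.
gauss_binom <- function(m, s) {
  co <- 1
  for (k in seq_len(s)) {
    # multiply by (1 - q^(m+k))
    co <- c(co, numeric(m + k)) - c(numeric(m + k), co)
    # divide by (1 - q^k): cumulative sums with stride k
    for (i in seq.int(k + 1L, length(co))) co[i] <- co[i] + co[i - k]
    co <- co[seq_len(length(co) - k)]
  }
  co
}

#' Exact permutation null of the Kendall score for a tied reference
#'
#' Distribution of `S` under uniformly random, untied rankings of the data
#' against a reference whose values form tie groups of the given sizes
#' (Harding-style convolution of Gaussian binomial coefficients).  The pmf
#' is symmetric about 0 and supported on `S = 2c - M`, `c = 0..M`, where
#' `M` is the number of reference-untied pairs.
#'
#' @param tie_sizes integer vector of reference tie-group sizes
#'   (`sum(tie_sizes) = n`, the number of samples).
#' @return Data frame with columns `S` and `prob`.
#' @examples
#' jtk_null(c(1, 1, 1))  # P(S = +-3) = 1/6, P(S = +-1) = 2/6
#' @export
jtk_null <- function(tie_sizes) {
  tie_sizes <- as.integer(tie_sizes)
  n <- sum(tie_sizes)
  if (n < 3L) stop("need at least 3 observations")
  if (any(tie_sizes < 1L)) stop("tie-group sizes must be >= 1")
  poly <- 1
  m <- 0L
  for (s in tie_sizes) {
    g <- gauss_binom(m, s)
    poly <- if (length(poly) == 1L) poly * g else
      if (length(g) == 1L) poly * g else convolve_poly(poly, g)
    m <- m + s
  }
  M <- (n^2 - sum(tie_sizes^2)) / 2
  stopifnot(length(poly) == M + 1)
  data.frame(S = 2 * seq(0, M) - M, prob = poly / sum(poly))
}

convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- seq.int(i, i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# exact two-sided tail probability P(|S_null| >= |s|) from a jtk_null table
jtk_tail_p <- function(null, s) {
  if (s == 0) return(1)
  sum(null$prob[abs(null$S) >= abs(s)])
}

# tie-group sizes of a reference vector (values rounded to kill fp fuzz)
ref_tie_sizes <- function(ref) {
  as.integer(table(round(ref, 9)))
}

#' JTK_CYCLE rhythmicity test for one series
#'
#' Scores the series against cosine references peaking at each lag on a
#' grid, collapses antiphase lags (half a period apart, whose references
#' are negations of one another) into one alternative scored by `|S|`,
#' evaluates the exact tie-aware null for each alternative, and returns
#' the Bonferroni-adjusted minimum tail probability.
#'
#' @param x numeric series values, one per design sample (`NA` allowed;
#'   analyzed on present samples).
#' @param design a [time_design()] for the samples of `x`.
#' @param period_h target period, hours (default 24, the circadian fixed
#'   period).
#' @param lag_step_h lag-grid step, hours; defaults to the design's
#'   sampling interval.
#' @return List with `p_value`, `best_lag_h` (peak-time estimate in
#'   `[0, period_h)`), `tau`, `S`, `n_alternatives` (Bonferroni count) and
#'   `degenerate`.
#' @export
jtk_test <- function(x, design, period_h = 24, lag_step_h = NULL) {
  ok <- is.finite(x)
  x <- x[ok]
  design <- design[ok, , drop = FALSE]
  times <- design$time_h
  if (length(unique(times)) < 4L) stop("need >= 4 distinct timepoints")
  if (is.null(lag_step_h)) {
    lag_step_h <- min(diff(sort(unique(times %% period_h))))
  }
  if (lag_step_h <= 0 || lag_step_h >= period_h) {
    stop("lag_step_h must be in (0, period_h)")
  }
  lags <- seq(0, period_h - lag_step_h / 2, by = lag_step_h)
  # canonical representative of each antiphase pair
  canon <- pmin(lags, (lags + period_h / 2) %% period_h)
  groups <- sort(unique(round(canon, 9)))

  if (length(unique(x)) == 1L) {
    return(list(p_value = 1, best_lag_h = NA_real_, tau = 0, S = 0L,
                n_alternatives = length(groups), degenerate = TRUE))
  }

  null_cache <- list()
  best <- list(p = Inf, lag = NA_real_, S = 0L, tau = 0)
  for (g in groups) {
    ref <- cos(2 * pi * (times - g) / period_h)
    ks <- kendall_s(x, ref)
    sizes <- ref_tie_sizes(ref)
    key <- paste(sort(sizes), collapse = ",")
    if (is.null(null_cache[[key]])) null_cache[[key]] <- jtk_null(sizes)
    p <- jtk_tail_p(null_cache[[key]], ks$S)
    if (p < best$p ||
        (p == best$p && abs(ks$S) > abs(best$S))) {
      lag <- if (ks$S >= 0) g else (g + period_h / 2) %% period_h
      best <- list(p = p, lag = lag, S = ks$S, tau = ks$tau)
    }
  }
  list(p_value = min(1, length(groups) * best$p),
       best_lag_h = best$lag,
       tau = abs(best$tau),
       S = best$S,
       n_alternatives = length(groups),
       degenerate = FALSE)
}
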