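# Lomb-Scargle periodogram test at a fixed target frequency.  The
# tau-offset (phase-shifted) form makes the power invariant to the time
# origin; replicates enter as repeated observations at the same time.

#' Normalized Lomb-Scargle power at a single period
#'
#' Mean-subtracted, variance-normalized periodogram power at frequency
#' `1/period_h`, using the tau-offset form.  Phase and amplitude come from
#' the implied single-harmonic least-squares fit ([harmonic_fit()]).
#'
#' @param x numeric series values (`NA` dropped).
#' @param design a [time_design()] for the samples of `x`.
#' @param period_h target period, hours.
#' @return List with `power_z` (>= 0), `phase_h` in `[0, period_h)`,
#'   `amplitude` (linear units) and `degenerate` (`TRUE` for zero-variance
#'   series, where `power_z = 0`).
#' @export
ls_power <- function(x, design, period_h = 24) {
  ok <- is.finite(x)
  x <- x[ok]
  t <- design$time_h[ok]
  n <- length(x)
  if (n < 4L || length(unique(t)) < 3L) {
    stop("need >= 4 samples at >= 3 distinct times")
  }
  if (period_h <= 0) stop("period_h must be > 0")
  s2 <- stats::var(x)
  if (s2 == 0) {
    return(list(power_z = 0, phase_h = NA_real_, amplitude = 0,
                degenerate = TRUE))
  }
  w <- 2 * pi / period_h
  s2w <- sum(sin(2 * w * t))
  c2w <- sum(cos(2 * w * t))
  tau <- if (abs(s2w) < 1e-12 && abs(c2w) < 1e-12) 0 else
    atan2(s2w, c2w) / (2 * w)
  y <- x - mean(x)
  ct <- cos(w * (t - tau))
  st <- sin(w * (t - tau))
  cc <- sum(ct^2)
  ss <- sum(st^2)
  yc <- sum(y * ct)
  ys <- sum(y * st)
  z <- ((if (cc > 0) yc^2 / cc else 0) +
        (if (ss > 0) ys^2 / ss else 0)) / (2 * s2)
  fit <- harmonic_fit(x, design[ok, , drop = FALSE], period_h)
  list(power_z = z, phase_h = fit$phase_h, amplitude = fit$amplitude,
       degenerate = FALSE)
}

#' Lomb-Scargle significance test at a fixed period
#'
#' The normalized power of Gaussian noise is asymptotically unit
#' exponential, so over `M` effectively independent frequencies
#' `p = 1 - (1 - exp(-z))^M`.  With the period fixed in advance (the
#' single-target design used here) `M = 1` and `p = exp(-z)`.
#'
#' @inheritParams ls_power
#' @param m_independent effective number of independent frequencies `M`
#'   (default 1: a single pre-specified period).  A period-scan over k
#'   frequencies should set `M = k`.
#' @return List with `p_value`, `power_z`, `phase_h`, `amplitude`,
#'   `degenerate`.
#' @examples
#' d <- sim_design()
#' y <- 100 + 50 * cos(2 * pi * (d$time_h - 16) / 24)
#' ls_test(y, d)  # maximal power, phase 16
#' @export
ls_test <- function(x, design, period_h = 24, m_independent = 1) {
  if (m_independent < 1) stop("m_independent must be >= 1")
  res <- ls_power(x, design, period_h)
  p <- if (res$degenerate) 1 else ls_significance(res$power_z, m_independent)
  c(list(p_value = p), res)
}

# Scargle false-alarm probability: 1 - (1 - e^-z)^M, stable for large z
ls_significance <- function(power_z, m_independent = 1) {
  lp1 <- log1p(-exp(-power_z))
  p <- if (lp1 == 0) 0 else -expm1(m_independent * lp1)
  min(1, max(0, p))
}
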