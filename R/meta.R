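# Integration of the per-method p-values (Fisher's method) and the
# per-transcript descriptive features: single-harmonic fit, baseline
# expression (bEXP), relative amplitude (rAMP), integrated phase.

#' Combine p-values by Fisher's method
#'
#' `X = -2 * sum(log(p_i))` is chi-square with `2k` degrees of freedom
#' under independent uniform nulls; returns the survival probability at
#' `X`.  With a single input the output equals that input.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @param clamp_zero if `TRUE`, p-values of exactly 0 (underflow from an
#'   upstream test) are clamped to `.Machine$double.xmin` before the log;
#'   if `FALSE` (default) a zero is an error.
#' @return Combined p-value in `(0, 1]`.
#' @examples
#' fisher_combine(c(0.5, 0.5))  # 0.5966
#' @export
fisher_combine <- function(p, clamp_zero = FALSE) {
  if (length(p) < 1L) stop("need at least one p-value")
  if (any(!is.finite(p)) || any(p > 1)) stop("p-values must be in (0, 1]")
  if (any(p <= 0)) {
    if (!clamp_zero) stop("p-values must be > 0 (set clamp_zero = TRUE)")
    p <- pmax(p, .Machine$double.xmin)
  }
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

#' Single-harmonic least-squares fit at a fixed period
#'
#' Ordinary least squares of `y = b + alpha*cos(wt) + beta*sin(wt)` with
#' `w = 2*pi/period_h`; amplitude `A = sqrt(alpha^2 + beta^2)` and peak
#' phase `phi = atan2(beta, alpha) * period_h / (2*pi)` mapped to
#' `[0, period_h)`.  On noiseless cosine input the generator parameters
#' are recovered exactly.
#'
#' @param x numeric series values (`NA` dropped).
#' @param design a [time_design()] for the samples of `x`.
#' @param period_h period of the fitted harmonic, hours.
#' @return List with `baseline`, `amplitude`, `phase_h` (`NA` with
#'   `degenerate = TRUE` when the fitted amplitude is numerically zero).
#' @export
harmonic_fit <- function(x, design, period_h = 24) {
  ok <- is.finite(x)
  x <- x[ok]
  t <- design$time_h[ok]
  if (length(unique(t)) < 3L) stop("need >= 3 distinct timepoints")
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * t), sin(w * t))
  if (qr(X)$rank < 3L) stop("rank-deficient design for harmonic fit")
  cf <- stats::lm.fit(X, x)$coefficients
  A <- sqrt(cf[2]^2 + cf[3]^2)
  scale <- max(1, abs(cf[1]))
  if (A < 1e-10 * scale) {
    return(list(baseline = unname(cf[1]), amplitude = 0,
                phase_h = NA_real_, degenerate = TRUE))
  }
  phi <- (atan2(cf[3], cf[2]) / w) %% period_h
  list(baseline = unname(cf[1]), amplitude = unname(A),
       phase_h = unname(phi), degenerate = FALSE)
}

#' Baseline expression (bEXP)
#'
#' Average expression level of a transcript within one period length: the
#' arithmetic mean of all sample values collected at times in
#' `[0, period_h)`.
#'
#' @inheritParams harmonic_fit
#' @return Numeric scalar.
#' @export
compute_bexp <- function(x, design, period_h = 24) {
  ok <- is.finite(x) & design$time_h >= 0 & design$time_h < period_h
  if (!any(ok)) stop("no samples within one period length")
  mean(x[ok])
}

#' Relative amplitude (rAMP)
#'
#' Oscillation amplitude normalized by baseline expression:
#' `amplitude / bexp`.  Dimensionless; invariant to rescaling the series.
#'
#' @param amplitude fitted amplitude, linear units (>= 0).
#' @param bexp baseline expression, linear units (> 0).
#' @return Numeric scalar.
#' @export
compute_ramp <- function(amplitude, bexp) {
  if (any(bexp <= 0)) stop("bexp must be > 0")
  amplitude / bexp
}

#' Amplitude-weighted circular mean of phases
#'
#' Converts each phase to a unit vector scaled by its weight, sums, and
#' maps the resultant angle back to hours in `[0, period_h)`.  Correctly
#' averages across the wrap (e.g. 23 h and 1 h give 0 h).
#'
#' @param phases numeric vector of phases in hours.
#' @param weights non-negative weights (e.g. per-method amplitudes).
#' @param period_h period, hours.
#' @return Mean phase in `[0, period_h)`, or `NA` if the total weight (or
#'   the resultant vector) is zero.
#' @export
integrate_phase <- function(phases, weights = rep(1, length(phases)),
                            period_h = 24) {
  if (length(phases) != length(weights)) stop("phases/weights length mismatch")
  ok <- is.finite(phases) & is.finite(weights) & weights > 0
  if (!any(ok)) return(NA_real_)
  ang <- 2 * pi * phases[ok] / period_h
  xs <- sum(weights[ok] * cos(ang))
  ys <- sum(weights[ok] * sin(ang))
  if (sqrt(xs^2 + ys^2) < 1e-12 * sum(weights[ok])) return(NA_real_)
  (atan2(ys, xs) * period_h / (2 * pi)) %% period_h
}

analyze_series <- function(x, design, period_h = 24,
                           methods = c("jtk", "ls"), ls_m = 1,
                           phase_method = c("weighted", "harmonic",
                                            "jtk", "ls")) {
  phase_method <- match.arg(phase_method)
  out <- list(p_jtk = NA_real_, p_ls = NA_real_, p_value = NA_real_,
              phase_h = NA_real_, amplitude = NA_real_, bexp = NA_real_,
              ramp = NA_real_, median_exp = NA_real_, jtk_lag_h = NA_real_,
              ls_power = NA_real_, flag = "ok")
  ok <- is.finite(x)
  out$median_exp <- if (any(ok)) stats::median(x[ok]) else NA_real_
  if (length(unique(design$time_h[ok])) < 4L) {
    out$flag <- "insufficient_data"
    return(out)
  }
  if (length(unique(x[ok])) == 1L) {
    out$flag <- "constant"
    out$p_jtk <- out$p_ls <- out$p_value <- 1
    out$amplitude <- 0
    out$bexp <- x[ok][1]
    out$ramp <- if (out$bexp > 0) 0 else NA_real_
    return(out)
  }
  fit <- harmonic_fit(x, design, period_h)
  out$amplitude <- fit$amplitude
  out$bexp <- compute_bexp(x, design, period_h)
  out$ramp <- if (out$bexp > 0) compute_ramp(fit$amplitude, out$bexp)
              else NA_real_

  ps <- numeric(0)
  phases <- numeric(0)
  wts <- numeric(0)
  if ("jtk" %in% methods) {
    j <- jtk_test(x, design, period_h)
    out$p_jtk <- j$p_value
    out$jtk_lag_h <- j$best_lag_h
    ps <- c(ps, max(j$p_value, .Machine$double.xmin))
    phases <- c(phases, j$best_lag_h)
    wts <- c(wts, fit$amplitude)
  }
  if ("ls" %in% methods) {
    l <- ls_test(x, design, period_h, m_independent = ls_m)
    out$p_ls <- l$p_value
    out$ls_power <- l$power_z
    ps <- c(ps, max(l$p_value, .Machine$double.xmin))
    phases <- c(phases, l$phase_h)
    wts <- c(wts, l$amplitude)
  }
  if (!length(ps)) stop("methods must include at least one of 'jtk', 'ls'")
  out$p_value <- fisher_combine(ps)
  out$phase_h <- switch(phase_method,
    weighted = integrate_phase(phases, wts, period_h),
    harmonic = fit$phase_h,
    jtk = if ("jtk" %in% methods) out$jtk_lag_h else NA_real_,
    ls = if ("ls" %in% methods) phases[length(phases)] else NA_real_)
  if (is.na(out$phase_h)) out$phase_h <- fit$phase_h
  out
}

#' Per-transcript, per-group rhythmicity analysis of a matrix
#'
#' Runs the rank test and/or the periodogram test on every transcript in
#' every group of the design, integrates p-values with Fisher's method,
#' and computes the descriptive features (phase, amplitude, bEXP, rAMP,
#' median expression).  Per-transcript failures are recorded in the
#' `flag` column and never abort the run.
#'
#' @param em an [expression_matrix()] (may contain several groups).
#' @param period_h target period, hours.
#' @param methods character subset of `c("jtk", "ls")`.
#' @param ls_m effective number of independent frequencies for the
#'   periodogram test.
#' @param phase_method how the reported phase is formed: amplitude-
#'   `"weighted"` circular mean of the method phases (default), the
#'   `"harmonic"` fit phase, or a single method's phase.
#' @return Data frame with one row per transcript x group: `transcript_id`,
#'   `group`, `p_jtk`, `p_ls`, `p_value` (integrated), `phase_h`,
#'   `amplitude`, `bexp`, `ramp`, `median_exp`, `jtk_lag_h`, `ls_power`,
#'   `flag`.
#' @export
analyze_matrix <- function(em, period_h = 24, methods = c("jtk", "ls"),
                           ls_m = 1, phase_method = "weighted") {
  if (!inherits(em, "expression_matrix")) stop("em must be an expression_matrix")
  groups <- unique(em$design$group)
  rows <- vector("list", nrow(em$values) * length(groups))
  k <- 0L
  for (g in groups) {
    sub <- subset_group(em, g)
    for (i in seq_len(nrow(sub$values))) {
      k <- k + 1L
      res <- tryCatch(
        analyze_series(sub$values[i, ], sub$design, period_h, methods,
                       ls_m, phase_method),
        error = function(e) {
          list(p_jtk = NA_real_, p_ls = NA_real_, p_value = NA_real_,
               phase_h = NA_real_, amplitude = NA_real_, bexp = NA_real_,
               ramp = NA_real_, median_exp = NA_real_,
               jtk_lag_h = NA_real_, ls_power = NA_real_,
               flag = paste0("error: ", conditionMessage(e)))
        })
      rows[[k]] <- data.frame(transcript_id = rownames(sub$values)[i],
                              group = g, res, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
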