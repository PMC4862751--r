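# Synthetic paired WT/KO expression experiments with known ground truth.
# Signal model: y(t) = [b + A*cos(2*pi*(t - phi)/period)] * eps_mult + eps_add,
# with eps_mult lognormal with mean 1 (sdlog = sigma_mult) and eps_add
# Gaussian with sd sd_add.  Non-cycling transcripts have A = 0.

#' Generate one synthetic transcript series
#'
#' @param design a [time_design()]; one value is generated per sample.
#' @param baseline baseline expression `b`, linear units (> 0).
#' @param amplitude cosine amplitude `A`, linear units
#'   (`0 <= A <= baseline`; `A = 0` gives a non-cycling transcript).
#' @param phase_h peak phase, hours in `[0, period_h)`.
#' @param period_h waveform period, hours.
#' @param sigma_mult sdlog of the mean-1 multiplicative lognormal noise
#'   (0 = off).
#' @param sd_add sd of the additive Gaussian noise (0 = off).  Positivity
#'   of the generated values requires `baseline - amplitude > 3 * sd_add`,
#'   which is enforced.
#' @param seed optional integer; when given, the series is a deterministic
#'   function of the seed (the caller's RNG state is untouched).
#' @return Numeric vector, one value per design sample.
#' @examples
#' d <- sim_design()
#' generate_transcript(d, 100, 50, 16, sigma_mult = 0, sd_add = 0)
#' @export
generate_transcript <- function(design, baseline, amplitude, phase_h,
                                period_h = 24, sigma_mult = 0.1,
                                sd_add = 1, seed = NULL) {
  if (baseline <= 0) stop("baseline must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude > baseline) {
    stop("amplitude > baseline would produce systematically negative signal")
  }
  if (sd_add > 0 && baseline - amplitude <= 3 * sd_add) {
    stop("baseline - amplitude must exceed 3 * sd_add for positive signal")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- nrow(design)
  signal <- baseline +
    amplitude * cos(2 * pi * (design$time_h - phase_h) / period_h)
  mult <- if (sigma_mult > 0) {
    stats::rlnorm(n, meanlog = -sigma_mult^2 / 2, sdlog = sigma_mult)
  } else rep(1, n)
  add <- if (sd_add > 0) stats::rnorm(n, 0, sd_add) else rep(0, n)
  signal * mult + add
}

#' Generate a paired WT/KO experiment with ground truth
#'
#' Transcripts fall into four classes: WT-only cyclers (cycle in WT, flat
#' in KO), common cyclers (cycle in both, with the KO phase delayed by
#' `phase_delay_ko` hours), KO-only cyclers, and never-cyclers.  Class
#' counts are exact (`round(frac * n)`).  Baselines are log-uniform on
#' `baseline_range`; relative amplitudes uniform on `ramp_range`; phases
#' uniform on `[0, period_h)`.
#'
#' @param n_transcripts total number of transcripts (> 0).
#' @param frac_wt_only,frac_common,frac_ko_only class fractions (their sum
#'   must be <= 1; the remainder never cycles).
#' @param phase_delay_ko KO phase delay for common cyclers, hours.
#' @param design_wt,design_ko per-group sampling designs; defaults are the
#'   one-day microarray design (6 timepoints x 4 h x 2 replicates).
#' @param period_h waveform period, hours.
#' @param baseline_range range of the log-uniform baseline draw.
#' @param ramp_range range of the uniform relative-amplitude (A/b) draw.
#' @param sigma_mult,sd_add noise parameters, see [generate_transcript()].
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return List with `wt`, `ko` ([expression_matrix()]s) and `truth`, a
#'   data frame with one row per transcript: `transcript_id`, `class`,
#'   `cycling_wt`, `cycling_ko`, `baseline`, `amplitude`, `ramp`,
#'   `phase_wt`, `phase_ko`.
#' @export
generate_experiment <- function(n_transcripts = 1000,
                                frac_wt_only = 0.3,
                                frac_common = 0.3,
                                frac_ko_only = 0,
                                phase_delay_ko = 2,
                                design_wt = sim_design(group = "WT"),
                                design_ko = sim_design(group = "KO"),
                                period_h = 24,
                                baseline_range = c(20, 2000),
                                ramp_range = c(0.2, 0.8),
                                sigma_mult = 0.1,
                                sd_add = 1,
                                seed = 1) {
  if (n_transcripts < 1L) stop("need at least one transcript")
  fr <- c(frac_wt_only, frac_common, frac_ko_only)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("class fractions must be >= 0 and sum to <= 1")
  }
  n_wt_only <- round(frac_wt_only * n_transcripts)
  n_common <- round(frac_common * n_transcripts)
  n_ko_only <- round(frac_ko_only * n_transcripts)
  n_none <- n_transcripts - n_wt_only - n_common - n_ko_only
  classes <- rep(c("wt_only", "common", "ko_only", "none"),
                 c(n_wt_only, n_common, n_ko_only, n_none))

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ids <- sprintf("t%05d", seq_len(n_transcripts))
  baseline <- 10^stats::runif(n_transcripts, log10(baseline_range[1]),
                              log10(baseline_range[2]))
  ramp <- stats::runif(n_transcripts, ramp_range[1], ramp_range[2])
  phase <- stats::runif(n_transcripts, 0, period_h)
  cycling_wt <- classes %in% c("wt_only", "common")
  cycling_ko <- classes %in% c("ko_only", "common")
  amp <- ifelse(cycling_wt | cycling_ko, ramp * baseline, 0)
  phase_wt <- ifelse(cycling_wt, phase, NA_real_)
  phase_ko <- ifelse(classes == "common",
                     (phase + phase_delay_ko) %% period_h,
                     ifelse(cycling_ko, phase, NA_real_))

  make_mat <- function(design, cycling, phases) {
    m <- matrix(NA_real_, n_transcripts, nrow(design),
                dimnames = list(ids, design$sample_id))
    for (i in seq_len(n_transcripts)) {
      m[i, ] <- generate_transcript(
        design,
        baseline = baseline[i],
        amplitude = if (cycling[i]) amp[i] else 0,
        phase_h = if (cycling[i]) phases[i] else 0,
        period_h = period_h, sigma_mult = sigma_mult, sd_add = sd_add)
    }
    expression_matrix(m, design)
  }
  wt <- make_mat(design_wt, cycling_wt, phase_wt)
  ko <- make_mat(design_ko, cycling_ko, phase_ko)

  truth <- data.frame(
    transcript_id = ids, class = classes,
    cycling_wt = cycling_wt, cycling_ko = cycling_ko,
    baseline = baseline, amplitude = amp, ramp = ifelse(amp > 0, ramp, 0),
    phase_wt = phase_wt, phase_ko = phase_ko,
    stringsAsFactors = FALSE)
  list(wt = wt, ko = ko, truth = truth)
}

#' Write a synthetic experiment to delimited text files
#'
#' Emits `matrix_wt.tsv`, `design_wt.tsv`, `matrix_ko.tsv`,
#' `design_ko.tsv` and `truth.tsv` under `dir`.
#'
#' @param exper result of [generate_experiment()].
#' @param dir output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_experiment <- function(exper, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(exper$wt, file.path(dir, "matrix_wt.tsv"),
                          file.path(dir, "design_wt.tsv"))
  write_expression_matrix(exper$ko, file.path(dir, "matrix_ko.tsv"),
                          file.path(dir, "design_ko.tsv"))
  utils::write.table(exper$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
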