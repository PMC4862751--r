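# WT-vs-KO differential cycling: the expressed-transcript filter, the
# stringent genotype-specific classification, the looser venn comparison,
# signed circular phase delays, and heatmap preparation.

#' Filter to expressed transcripts
#'
#' Keeps rows whose baseline expression exceeds `bexp_min` (strictly:
#' "larger than").  The default 101.6 is the linear-scale expression
#' threshold used to call a transcript expressed on the arrays this
#' pipeline targets.
#'
#' @param results data frame with a `bexp` column ([analyze_matrix()]).
#' @param bexp_min strict lower bound on bEXP.
#' @return The subset of `results` with `bexp > bexp_min`.
#' @export
expressed_filter <- function(results, bexp_min = 101.6) {
  results[!is.na(results$bexp) & results$bexp > bexp_min, , drop = FALSE]
}

#' Classify genotype-specific loss of cycling
#'
#' Applies the stringent two-threshold rule: a transcript is WT-specific
#' when it is expressed, cyclic in WT (`p < p_cyclic`) and non-cyclic in
#' KO (`p > p_noncyclic`); symmetrically for KO-specific.  Transcripts
#' cyclic in both at the looser `p_venn` threshold are `common` (these
#' also get a signed phase delay); expressed transcripts matching no rule
#' are `neither`; transcripts at or below the bEXP threshold in both
#' genotypes are `not_expressed`.  Labels are mutually exclusive and
#' exhaustive.
#'
#' @param wt_results,ko_results per-genotype results from
#'   [analyze_matrix()]; must cover the same transcripts.  Transcripts
#'   present in only one genotype are flagged and excluded.
#' @param p_cyclic stringent cyclic threshold (default 0.01).
#' @param p_noncyclic non-cyclic threshold (default 0.8).
#' @param p_venn loose cyclic threshold for the `common` label
#'   (default 0.05).
#' @param bexp_min expressed-transcript threshold ([expressed_filter()]);
#'   a transcript counts as expressed if it passes in either genotype.
#' @param period_h period for the phase-delay computation, hours.
#' @return Data frame with `transcript_id`, `label` (factor with levels
#'   `not_expressed`, `wt_specific`, `ko_specific`, `common`, `neither`),
#'   `wt_p`, `ko_p`, `wt_phase`, `ko_phase`, `phase_delay_h` (present iff
#'   `common`).
#' @export
classify_cycling <- function(wt_results, ko_results, p_cyclic = 0.01,
                             p_noncyclic = 0.8, p_venn = 0.05,
                             bexp_min = 101.6, period_h = 24) {
  only <- union(setdiff(wt_results$transcript_id, ko_results$transcript_id),
                setdiff(ko_results$transcript_id, wt_results$transcript_id))
  if (length(only)) {
    warning(length(only), " transcript(s) present in only one genotype ",
            "were excluded")
  }
  m <- merge(
    wt_results[, c("transcript_id", "p_value", "phase_h", "bexp")],
    ko_results[, c("transcript_id", "p_value", "phase_h", "bexp")],
    by = "transcript_id", suffixes = c("_wt", "_ko"))
  expressed <- (!is.na(m$bexp_wt) & m$bexp_wt > bexp_min) |
               (!is.na(m$bexp_ko) & m$bexp_ko > bexp_min)
  wt_p <- m$p_value_wt
  ko_p <- m$p_value_ko
  lab <- rep("neither", nrow(m))
  lab[!expressed | is.na(wt_p) | is.na(ko_p)] <- "not_expressed"
  usable <- expressed & !is.na(wt_p) & !is.na(ko_p)
  lab[usable & wt_p < p_venn & ko_p < p_venn] <- "common"
  lab[usable & wt_p < p_cyclic & ko_p > p_noncyclic] <- "wt_specific"
  lab[usable & ko_p < p_cyclic & wt_p > p_noncyclic] <- "ko_specific"
  delay <- rep(NA_real_, nrow(m))
  is_common <- lab == "common"
  delay[is_common] <- phase_delay(m$phase_h_wt[is_common],
                                  m$phase_h_ko[is_common],
                                  period_h)$delay_h
  data.frame(
    transcript_id = m$transcript_id,
    label = factor(lab, levels = c("not_expressed", "wt_specific",
                                   "ko_specific", "common", "neither")),
    wt_p = wt_p, ko_p = ko_p,
    wt_phase = m$phase_h_wt, ko_phase = m$phase_h_ko,
    phase_delay_h = delay,
    stringsAsFactors = FALSE)
}

#' Venn counts of cycling transcripts at a loose threshold
#'
#' @inheritParams classify_cycling
#' @param bexp_min expressed filter applied (in either genotype) before
#'   counting; set to `-Inf` to count the full universe.
#' @return Named list: `n_wt_cyclic`, `n_ko_cyclic`, `n_common`.
#' @export
venn_counts <- function(wt_results, ko_results, p_venn = 0.05,
                        bexp_min = 101.6) {
  m <- merge(wt_results[, c("transcript_id", "p_value", "bexp")],
             ko_results[, c("transcript_id", "p_value", "bexp")],
             by = "transcript_id", suffixes = c("_wt", "_ko"))
  expressed <- (!is.na(m$bexp_wt) & m$bexp_wt > bexp_min) |
               (!is.na(m$bexp_ko) & m$bexp_ko > bexp_min)
  m <- m[expressed, , drop = FALSE]
  wt_cyc <- !is.na(m$p_value_wt) & m$p_value_wt < p_venn
  ko_cyc <- !is.na(m$p_value_ko) & m$p_value_ko < p_venn
  list(n_wt_cyclic = sum(wt_cyc), n_ko_cyclic = sum(ko_cyc),
       n_common = sum(wt_cyc & ko_cyc))
}

#' Signed circular phase delay KO - WT
#'
#' `delay = ((phi_ko - phi_wt + period/2) mod period) - period/2`, in
#' `(-period/2, period/2]`; positive values mean the KO peak comes later.
#' The summary holds the median delay and a two-sided sign-test p-value
#' for a systematic (nonzero-median) shift.
#'
#' @param phase_wt,phase_ko numeric phase vectors, hours in
#'   `[0, period_h)`.
#' @param period_h period, hours.
#' @return List with `delay_h` (per-transcript signed delays),
#'   `median_delay_h` and `sign_test_p`.
#' @export
phase_delay <- function(phase_wt, phase_ko, period_h = 24) {
  d <- ((phase_ko - phase_wt + period_h / 2) %% period_h) - period_h / 2
  d[!is.na(d) & d == -period_h / 2] <- period_h / 2
  ok <- !is.na(d)
  pos <- sum(d[ok] > 0)
  neg <- sum(d[ok] < 0)
  p <- if (pos + neg > 0) {
    stats::binom.test(pos, pos + neg)$p.value
  } else NA_real_
  list(delay_h = d,
       median_delay_h = if (any(ok)) stats::median(d[ok]) else NA_real_,
       sign_test_p = p)
}

#' Prepare a phase-sorted, median-normalized heatmap matrix
#'
#' Replicates are averaged per timepoint, each row is divided by its
#' median (of the averaged values), and rows are sorted by ascending phase
#' in the chosen group's results.  Rows with a non-positive median are
#' flagged and dropped.
#'
#' @param em an [expression_matrix()] restricted to one group, or a
#'   multi-group matrix with `order_group` naming the group to use.
#' @param results results from [analyze_matrix()] carrying the phases.
#' @param order_group group label whose phases order the rows.
#' @return List with `matrix` (transcripts x timepoints, row median 1),
#'   `phase_h` (row order phases) and `dropped` (ids of flagged rows).
#' @export
heatmap_prepare <- function(em, results, order_group = "WT") {
  sub <- if (order_group %in% em$design$group) subset_group(em, order_group)
         else stop("group '", order_group, "' not in matrix design")
  times <- sort(unique(sub$design$time_h))
  avg <- sapply(times, function(tt) {
    cols <- sub$design$time_h == tt
    rowMeans(sub$values[, cols, drop = FALSE], na.rm = TRUE)
  })
  colnames(avg) <- sprintf("ZT%g", times)
  med <- apply(avg, 1, stats::median)
  keep <- is.finite(med) & med > 0
  dropped <- rownames(avg)[!keep]
  avg <- avg[keep, , drop = FALSE] / med[keep]
  res <- results[results$group == order_group, c("transcript_id", "phase_h")]
  phase <- res$phase_h[match(rownames(avg), res$transcript_id)]
  ord <- order(phase, na.last = TRUE)
  list(matrix = avg[ord, , drop = FALSE], phase_h = phase[ord],
       dropped = dropped)
}
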