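#' Sampling design for an expression time course
#'
#' A `time_design` records, for every sample (array, library, qPCR well),
#' its collection time in hours (Zeitgeber Time), a replicate index and a
#' group (genotype/condition) label.  Times are 0-based hours within the
#' experiment; no date arithmetic is performed.
#'
#' @param sample_id character vector of unique sample labels.
#' @param time_h numeric vector of collection times in hours, one per sample.
#' @param replicate integer vector of replicate indices, one per sample.
#' @param group character vector of group labels, one per sample.
#'
#' @return A data frame of class `time_design` with columns `sample_id`,
#'   `time_h`, `replicate`, `group`.
#' @examples
#' time_design(c("a", "b", "c", "d"), c(0, 0, 12, 12), c(1, 2, 1, 2), "WT")
#' @export
time_design <- function(sample_id, time_h, replicate, group) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (n == 0L) stop("design must contain at least one sample")
  time_h <- as.numeric(time_h)
  replicate <- as.integer(replicate)
  group <- as.character(group)
  if (length(group) == 1L) group <- rep(group, n)
  if (length(time_h) != n || length(replicate) != n || length(group) != n) {
    stop("sample_id, time_h, replicate and group must have equal length")
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (any(!is.finite(time_h)) || any(time_h < 0)) {
    stop("collection times must be finite and >= 0")
  }
  d <- data.frame(sample_id = sample_id, time_h = time_h,
                  replicate = replicate, group = group,
                  stringsAsFactors = FALSE)
  for (g in unique(group)) {
    if (length(unique(time_h[group == g])) < 2L) {
      stop("group '", g, "' has fewer than 2 distinct timepoints")
    }
  }
  class(d) <- c("time_design", "data.frame")
  d
}

#' Standard even sampling designs
#'
#' Convenience constructor for the evenly spaced designs used throughout:
#' `n_timepoints` collections every `interval_h` hours starting at ZT0, with
#' `n_reps` replicates per timepoint.  The defaults (6 timepoints x 4 h x
#' 2 replicates) match a one-day microarray collection; qPCR series
#' typically use 3-4 replicates.
#'
#' @param n_timepoints number of distinct collection times.
#' @param interval_h spacing between collections, hours.
#' @param n_reps replicates per timepoint.
#' @param group group label for all samples.
#'
#' @return A [time_design()].
#' @examples
#' sim_design()                 # 6 x 4 h x 2 reps, "WT"
#' sim_design(n_reps = 4, group = "KO")
#' @export
sim_design <- function(n_timepoints = 6, interval_h = 4, n_reps = 2,
                       group = "WT") {
  times <- rep(seq(0, by = interval_h, length.out = n_timepoints),
               each = n_reps)
  reps <- rep(seq_len(n_reps), times = n_timepoints)
  ids <- sprintf("%s_ZT%02d_r%d", group, as.integer(times), reps)
  time_design(ids, times, reps, group)
}

#' Expression matrix bound to its sampling design
#'
#' @param values numeric matrix, transcripts x samples, linear scale.
#'   Row names are transcript ids; column names must match
#'   `design$sample_id` (columns are reordered to the design order).
#'   Missing values are `NA`, never silent zeros.
#' @param design a [time_design()] covering every column.
#'
#' @return A list of class `expression_matrix` with elements `values`
#'   (matrix, columns in design order) and `design`.
#' @export
expression_matrix <- function(values, design) {
  if (!inherits(design, "time_design")) stop("design must be a time_design")
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("t%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    stop("matrix columns must be named with sample ids")
  }
  missing_cols <- setdiff(design$sample_id, colnames(values))
  if (length(missing_cols)) {
    stop("design sample(s) absent from matrix: ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(colnames(values), design$sample_id)
  if (length(extra)) {
    stop("matrix sample(s) absent from design: ",
         paste(extra, collapse = ", "))
  }
  values <- values[, design$sample_id, drop = FALSE]
  storage.mode(values) <- "double"
  if (any(!is.finite(values) & !is.na(values))) {
    stop("expression values must be finite or NA")
  }
  structure(list(values = values, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$design$group), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# subset samples of an expression_matrix by group label
subset_group <- function(em, group) {
  keep <- em$design$group == group
  if (!any(keep)) stop("no samples in group '", group, "'")
  d <- em$design[keep, , drop = FALSE]
  class(d) <- c("time_design", "data.frame")
  structure(list(values = em$values[, keep, drop = FALSE], design = d),
            class = "expression_matrix")
}
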