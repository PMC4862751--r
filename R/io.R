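# Delimited-text readers/writers for expression matrices, design tables and
# per-transcript results.  Delimiter is chosen from the file extension:
# ".csv" -> comma, anything else -> tab.  Encoding is UTF-8 throughout.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_generic <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"", fileEncoding = "UTF-8")
}

#' Read a sampling-design table
#'
#' The design file must carry columns `sample_id`, `time_h`, `replicate`,
#' `group` (extra columns are ignored).
#'
#' @param path path to a .tsv or .csv design table.
#' @return A [time_design()].
#' @export
read_design <- function(path) {
  d <- read_table_generic(path)
  need <- c("sample_id", "time_h", "replicate", "group")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("design file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  time_design(d$sample_id, d$time_h, d$replicate, d$group)
}

#' Read an expression matrix and bind it to its design
#'
#' The matrix file is a delimited table whose header row holds sample ids
#' and whose first column holds transcript ids.  Columns are reordered to
#' match the design, so the sample-time association is independent of the
#' column order on disk.
#'
#' @param path path to the expression table (.tsv or .csv).
#' @param design_path path to the design table (see [read_design()]), or a
#'   `time_design` object.
#' @param delog2 if `TRUE`, values are assumed log2 and converted to the
#'   linear scale by `2^x`.  All downstream statistics (bEXP, rAMP, the
#'   expressed-transcript filter) are defined on the linear scale.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, design_path, delog2 = FALSE) {
  design <- if (inherits(design_path, "time_design")) design_path
            else read_design(design_path)
  tab <- read_table_generic(path)
  if (ncol(tab) < 2L) stop("expression table needs an id column plus samples")
  ids <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                     v[bad[1L]], bad[1L], names(vals)[j], path))
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (delog2) m <- 2^m
  expression_matrix(m, design)
}

#' Write an expression matrix (with its design) to delimited text
#'
#' @param em an [expression_matrix()].
#' @param path output path for the matrix table.
#' @param design_path optional output path for the design table.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(em, path, design_path = NULL) {
  sep <- delim_for(path)
  tab <- data.frame(transcript_id = rownames(em$values),
                    em$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(design_path)) {
    utils::write.table(as.data.frame(em$design), design_path,
                       sep = delim_for(design_path), quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Write per-transcript rhythm statistics
#'
#' One row per transcript and group, mirroring the per-gene statistics a
#' rhythmicity screen reports: method p-values, integrated p, phase,
#' amplitude, bEXP, rAMP and median expression.  Numeric columns keep full
#' double precision (well beyond 4 significant digits).
#'
#' @param results data frame as returned by [analyze_matrix()].
#' @param path output path (.tsv or .csv).
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a non-empty data frame")
  }
  utils::write.table(results, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path path to the results table.
#' @return A data frame.
#' @export
read_results_table <- function(path) {
  read_table_generic(path)
}
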