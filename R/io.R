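# File-format plumbing: CSV for peak tables (fragment-analysis exports
# are CSV-like), TSV for matrices and summaries; UTF-8, headers
# mandatory; a JSON run manifest records config, seed and file digests so
# any result is re-derivable.

#' Write / read a TD peak table (CSV)
#'
#' Columns: `lineage_id`, `replicate`, `fragment_bp`, `height`.
#'
#' @param peaks A peak table data.frame.
#' @param path File path.
#' @return `path` (writer, invisibly) / the peak table (reader).
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks)[, c("lineage_id", "replicate",
                                            "fragment_bp", "height")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  peaks <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("lineage_id", "replicate", "fragment_bp", "height")
  if (!all(req %in% names(peaks))) {
    stop("peak CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  peaks$lineage_id <- as.character(peaks$lineage_id)
  peaks$replicate <- as.integer(peaks$replicate)
  peaks$fragment_bp <- as.integer(peaks$fragment_bp)
  class(peaks) <- c("peak_table", "data.frame")
  peaks
}

#' Write / read a presence/absence matrix (TSV)
#'
#' Layout mirrors the per-family data matrix: one row per lineage with a
#' treatment column, then one column per ancestral fragment size (header
#' = size in bp), entries 1 (present) / 0 (absent).
#'
#' @param matrix A `presence_matrix`.
#' @param path File path.
#' @return `path` (writer, invisibly) / a `presence_matrix` (reader).
#' @export
write_presence_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "presence_matrix"))
  df <- data.frame(lineage_id = rownames(matrix$presence),
                   treatment = unname(matrix$treatment),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(matrix$presence + 0L))
  names(df) <- c("lineage_id", "treatment", colnames(matrix$presence))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("lineage_id", "treatment") %in% names(df))) {
    stop("matrix TSV must have lineage_id and treatment columns",
         call. = FALSE)
  }
  size_cols <- setdiff(names(df), c("lineage_id", "treatment"))
  m <- as.matrix(df[, size_cols, drop = FALSE]) == 1
  rownames(m) <- df$lineage_id
  structure(list(presence = m,
                 treatment = stats::setNames(df$treatment, df$lineage_id)),
            class = "presence_matrix")
}

#' Write / read peak calls (CSV)
#'
#' @param calls Output of [classify_new_peaks()].
#' @param path File path.
#' @return `path` (writer, invisibly) / the calls (reader).
#' @export
write_peak_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peak_calls
#' @export
read_peak_calls <- function(path) {
  calls <- utils::read.csv(path, stringsAsFactors = FALSE)
  calls$lineage_id <- as.character(calls$lineage_id)
  calls
}

#' Write a cohort's event log (TSV, one row per event)
#'
#' @param cohort An `ma_cohort`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(cohort, path) {
  utils::write.table(cohort_events(cohort), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read lineage metadata (TSV)
#'
#' @param cohort An `ma_cohort` (writer) or path (reader).
#' @param path File path.
#' @return `path` (writer, invisibly) / metadata data.frame (reader).
#' @export
write_lineage_table <- function(cohort, path) {
  utils::write.table(cohort_metadata(cohort), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lineage_table
#' @export
read_lineage_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(selfing_generations = "character"))
  df$lineage_id <- as.character(df$lineage_id)
  df
}

#' Write a run manifest (JSON)
#'
#' Records the config snapshot, seed, package version, timestamps and an
#' md5 digest of every output file, making the run re-derivable.
#'
#' @param config The `sim_config` (or NULL for downstream stages).
#' @param files Character vector of output file paths.
#' @param path Manifest path.
#' @param stage Stage name.
#' @param params Extra stage parameters to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, files, path, stage = "simulate",
                           params = list()) {
  digests <- tools::md5sum(files)
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("temaline")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (!is.null(config)) config$seed else NULL,
    config = if (!is.null(config)) unclass(config) else NULL,
    params = params,
    files = as.list(stats::setNames(unname(digests), basename(files)))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
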