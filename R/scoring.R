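# Scoring of triplicate TD peak tables into the presence/absence matrix
# and calls of losses, germline gains and putative somatic gains.
# Rubric: losses are absent bands at ancestrally occupied sizes; a new
# peak is a germline gain only if present in all three replicates; a
# robust new peak missing from at least one replicate is a putative
# somatic insertion.

#' Bin peaks across replicates into per-lineage replicate counts
#'
#' Peaks below `height_threshold` are discarded; surviving peaks are
#' merged across replicates when their sizes differ by at most
#' `size_tolerance` bp (default 0: exact integer match, appropriate for
#' the simulator's integer fragment sizes; real fragment-analysis exports
#' may need 1 bp). With a positive tolerance, sizes are clustered by
#' sorting and splitting at gaps larger than the tolerance, and each bin
#' is labelled by the rounded mean size of its members.
#'
#' @param peaks A peak table (columns `lineage_id`, `replicate`,
#'   `fragment_bp`, `height`).
#' @param height_threshold Minimum peak height retained.
#' @param size_tolerance Maximum bp gap merged into one bin.
#' @return A data.frame with columns `lineage_id`, `fragment_bp`,
#'   `n_replicates` (in 1..3).
#' @export
bin_peaks <- function(peaks, height_threshold = 0, size_tolerance = 0) {
  req <- c("lineage_id", "replicate", "fragment_bp", "height")
  if (!all(req %in% names(peaks))) {
    stop("peak table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  # replicate structure is checked before height filtering: a lineage
  # run in fewer than three reactions cannot be scored by the rubric
  reps <- tapply(peaks$replicate, peaks$lineage_id,
                 function(r) length(unique(r)))
  bad <- names(reps)[reps != 3L]
  if (length(bad)) {
    stop("lineage(s) without exactly 3 TD replicates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- peaks[peaks$height >= height_threshold, , drop = FALSE]
  if (!nrow(keep)) {
    return(data.frame(lineage_id = character(), fragment_bp = integer(),
                      n_replicates = integer(), stringsAsFactors = FALSE))
  }
  size <- keep$fragment_bp
  if (size_tolerance > 0) {
    u <- sort(unique(size))
    bin_id <- cumsum(c(1L, diff(u) > size_tolerance))
    centers <- round(tapply(u, bin_id, mean))
    size <- as.integer(centers[bin_id[match(size, u)]])
  }
  key <- paste(keep$lineage_id, size, sep = "\r")
  counts <- tapply(keep$replicate, key, function(r) length(unique(r)))
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- data.frame(
    lineage_id = vapply(parts, `[`, "", 1L),
    fragment_bp = as.integer(vapply(parts, `[`, "", 2L)),
    n_replicates = as.integer(counts),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$lineage_id, out$fragment_bp), , drop = FALSE]
}

#' Identify ancestrally occupied loci
#'
#' All lines descend from a single ancestor, so a fragment size that is
#' fully replicable (3/3 reactions) in a large share of lineages must
#' have been occupied in that ancestor. The default share of 0.5 is
#' robust to the ~25% segregational loss expected at heterozygous loci in
#' selfed lines.
#'
#' @param counts Output of [bin_peaks()].
#' @param min_share Minimum fraction of lineages in which the size is
#'   replicable for it to be called ancestral.
#' @param n_lineages Total lineages assayed; defaults to the number of
#'   distinct lineages in `counts`.
#' @return Sorted integer vector of ancestral fragment sizes.
#' @export
identify_ancestral_loci <- function(counts, min_share = 0.5,
                                    n_lineages = NULL) {
  if (is.null(n_lineages)) n_lineages <- length(unique(counts$lineage_id))
  if (n_lineages < 2L) {
    stop("ancestral loci are defined by recurrence across lineages; ",
         "need at least 2 lineages", call. = FALSE)
  }
  full <- counts[counts$n_replicates == 3L, , drop = FALSE]
  n_with <- table(full$fragment_bp)
  sort(as.integer(names(n_with)[n_with >= min_share * n_lineages]))
}

#' Classify retained peaks into ancestral / germline gain / somatic
#'
#' Sizes in the ancestral set are ancestral insertions; a novel size
#' replicable in all three reactions is a new germline insertion; a novel
#' size seen in one or two reactions is a putative somatic insertion.
#'
#' @param counts Output of [bin_peaks()].
#' @param ancestral Ancestral fragment sizes
#'   (from [identify_ancestral_loci()]).
#' @return A data.frame of peak calls: `lineage_id`, `fragment_bp`,
#'   `category`, `replicate_count`.
#' @export
classify_new_peaks <- function(counts, ancestral) {
  category <- ifelse(counts$fragment_bp %in% ancestral, "ancestral",
                     ifelse(counts$n_replicates == 3L,
                            "germline_gain", "somatic"))
  data.frame(
    lineage_id = counts$lineage_id,
    fragment_bp = counts$fragment_bp,
    category = category,
    replicate_count = counts$n_replicates,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Build the lineages x ancestral-loci presence/absence matrix
#'
#' One row per lineage, one column per ancestral fragment size; an entry
#' is absent exactly when no peak at that size was retained in any of the
#' lineage's three replicates. Losses are the absent entries.
#'
#' @param counts Output of [bin_peaks()].
#' @param ancestral Ancestral fragment sizes.
#' @param treatments Named character vector mapping every lineage id to
#'   `"sexual"` or `"asexual"`; its names define the matrix rows (so
#'   lineages that lost every band still appear).
#' @return A list of class `presence_matrix` with elements `presence`
#'   (logical matrix) and `treatment`.
#' @export
build_matrix <- function(counts, ancestral, treatments) {
  if (is.null(names(treatments)) || any(!nzchar(names(treatments)))) {
    stop("treatments must be a named vector (names = lineage ids)",
         call. = FALSE)
  }
  missing_tr <- setdiff(unique(counts$lineage_id), names(treatments))
  if (length(missing_tr)) {
    stop("lineage(s) missing from treatment map: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  ancestral <- sort(as.integer(ancestral))
  ids <- names(treatments)
  m <- matrix(FALSE, nrow = length(ids), ncol = length(ancestral),
              dimnames = list(ids, as.character(ancestral)))
  hit <- counts[counts$fragment_bp %in% ancestral, , drop = FALSE]
  if (nrow(hit)) {
    m[cbind(hit$lineage_id, as.character(hit$fragment_bp))] <- TRUE
  }
  structure(list(presence = m,
                 treatment = stats::setNames(as.character(treatments), ids)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("TD presence/absence matrix: ", nrow(x$presence), " lineages x ",
      ncol(x$presence), " ancestral loci; ", sum(!x$presence),
      " absent entries (losses)\n", sep = "")
  invisible(x)
}

#' Identify high-loss loci
#'
#' Ancestral loci at which losses were observed in more than
#' `min_lineages` lineages (strict inequality) — the signature of loci
#' that were heterozygous in the ancestor and segregated after sex.
#'
#' @param matrix A `presence_matrix`.
#' @param min_lineages Loss-count threshold (strictly exceeded).
#' @return Integer vector of high-loss fragment sizes.
#' @export
identify_high_loss_loci <- function(matrix, min_lineages = 3) {
  stopifnot(inherits(matrix, "presence_matrix"))
  losses <- colSums(!matrix$presence)
  as.integer(colnames(matrix$presence)[losses > min_lineages])
}
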