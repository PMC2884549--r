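# Emulation of triplicate transposon-display (TD) fragment-analysis
# output. TD reports presence of a fragment size, not allele dosage:
# heterozygous and homozygous loci produce identical peaks, and somatic
# insertions show up as robust peaks that fail to replicate across the
# three reactions.

#' Emulate triplicate transposon-display peak tables for a cohort
#'
#' Every locus carrying at least one copy yields a peak at its fragment
#' size in all three replicates (dosage is invisible to TD). Somatic
#' insertions are drawn once at assay time, with an expected count of
#' `somatic_rate` per occupied locus; each somatic peak appears in each
#' replicate independently with `somatic_replicate_detection`, resampled
#' so that it is seen in at least one but never all three replicates.
#' Germline peak heights are drawn taller than somatic ones on average
#' (both log-normal).
#'
#' @param cohort An `ma_cohort` (or plain list of `ma_lineage`).
#' @param config The [sim_config()] used to simulate the cohort.
#' @return A data.frame of class `peak_table` with columns `lineage_id`,
#'   `replicate`, `fragment_bp`, `height` (one row per peak per
#'   replicate), plus a `somatic_truth` attribute listing the true
#'   somatic fragment sizes per lineage.
#' @export
emulate_td <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  out <- vector("list", length(cohort))
  truth <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    line <- cohort[[i]]
    set.seed(lineage_seed(config$seed, i, stage = 1L))
    occ <- line$loci[line$loci$copies >= 1L, , drop = FALSE]
    n_occ <- nrow(occ)
    germ <- if (n_occ) {
      data.frame(
        lineage_id = line$lineage_id,
        replicate = rep(1:3, each = n_occ),
        fragment_bp = rep(occ$fragment_bp, 3L),
        height = stats::rlnorm(3L * n_occ, config$height_meanlog_germline,
                               config$height_sdlog),
        stringsAsFactors = FALSE
      )
    } else {
      NULL
    }
    som <- NULL
    n_som <- if (config$somatic_rate > 0 && n_occ > 0) {
      stats::rpois(1L, config$somatic_rate * n_occ)
    } else {
      0L
    }
    if (n_som > 0L) {
      sizes <- draw_new_sizes(n_som, config$fragment_size_range,
                              line$loci$fragment_bp)
      reps <- lapply(seq_len(n_som), function(j) {
        repeat {
          pres <- which(stats::runif(3) < config$somatic_replicate_detection)
          if (length(pres) >= 1L && length(pres) <= 2L) return(pres)
        }
      })
      n_rows <- lengths(reps)
      som <- data.frame(
        lineage_id = line$lineage_id,
        replicate = unlist(reps),
        fragment_bp = rep(as.integer(sizes), n_rows),
        height = stats::rlnorm(sum(n_rows), config$height_meanlog_somatic,
                               config$height_sdlog),
        stringsAsFactors = FALSE
      )
      truth[[i]] <- data.frame(lineage_id = line$lineage_id,
                               fragment_bp = as.integer(sizes),
                               stringsAsFactors = FALSE)
    }
    out[[i]] <- rbind(germ, som)
  }
  peaks <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(peaks)) {
    peaks <- data.frame(lineage_id = character(), replicate = integer(),
                        fragment_bp = integer(), height = numeric(),
                        stringsAsFactors = FALSE)
  }
  # lineages whose loci are all lost still ran three (empty) reactions;
  # scoring learns replicate structure from the metadata, not from here
  rownames(peaks) <- NULL
  truth <- truth[!vapply(truth, is.null, logical(1))]
  attr(peaks, "somatic_truth") <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(lineage_id = character(), fragment_bp = integer(),
               stringsAsFactors = FALSE)
  }
  class(peaks) <- c("peak_table", "data.frame")
  peaks
}
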