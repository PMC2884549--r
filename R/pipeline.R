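# Pipeline stages binding simulation, scoring and rate estimation into
# one reproducible run: each stage reads/writes plain-text files and a
# JSON manifest; a fixed config + seed reproduces every byte.

msg <- function(quiet, ...) if (!quiet) message(...)

#' Simulate a cohort and write its files
#'
#' Writes `lineages.tsv`, `events.tsv`, `peaks.csv` and `manifest.json`
#' to `out_dir`. Rerunning with the same config and seed reproduces the
#' files byte-for-byte.
#'
#' @param config A [sim_config()], or the path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the config's.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the cohort, peaks and file paths.
#' @export
run_simulate <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    config$seed <- seed
    config <- validate_sim_config(unclass(config))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  msg(quiet, "[simulate] family ", config$family_id, ", seed ", config$seed,
      ": ", config$n_asexual + config$n_sexual, " lineages")
  cohort <- run_experiment(config)
  peaks <- emulate_td(cohort, config)
  paths <- file.path(out_dir, c("lineages.tsv", "events.tsv", "peaks.csv"))
  write_lineage_table(cohort, paths[1])
  write_event_log(cohort, paths[2])
  write_peak_table(peaks, paths[3])
  write_manifest(config, paths, file.path(out_dir, "manifest.json"),
                 stage = "simulate")
  msg(quiet, "[simulate] wrote ", nrow(peaks), " peak rows to ", out_dir)
  invisible(list(cohort = cohort, peaks = peaks, config = config,
                 files = paths))
}

#' Score a peak table into matrix and calls
#'
#' Bins triplicate peaks, identifies ancestral loci, classifies new peaks
#' and writes `matrix.tsv` (presence/absence, treatment-labelled) and
#' `calls.csv` to `out_dir`.
#'
#' @param peaks_csv Path to a peak-table CSV, or a peak table.
#' @param lineages_tsv Path to the lineage metadata TSV, or the metadata
#'   data.frame (supplies treatment labels and the full lineage roster).
#' @param out_dir Output directory.
#' @param height_threshold,size_tolerance Passed to [bin_peaks()].
#' @param min_share Passed to [identify_ancestral_loci()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the matrix, calls and file paths.
#' @export
run_score <- function(peaks_csv, lineages_tsv, out_dir,
                      height_threshold = 50, size_tolerance = 0,
                      min_share = 0.5, quiet = FALSE) {
  peaks <- if (is.character(peaks_csv)) read_peak_table(peaks_csv) else
    peaks_csv
  meta <- if (is.character(lineages_tsv)) read_lineage_table(lineages_tsv)
    else lineages_tsv
  treatments <- stats::setNames(meta$treatment, meta$lineage_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- bin_peaks(peaks, height_threshold, size_tolerance)
  ancestral <- identify_ancestral_loci(counts, min_share,
                                       n_lineages = nrow(meta))
  calls <- classify_new_peaks(counts, ancestral)
  mat <- build_matrix(counts, ancestral, treatments)
  paths <- file.path(out_dir, c("matrix.tsv", "calls.csv"))
  write_presence_matrix(mat, paths[1])
  write_peak_calls(calls, paths[2])
  write_manifest(NULL, paths, file.path(out_dir, "score_manifest.json"),
                 stage = "score",
                 params = list(height_threshold = height_threshold,
                               size_tolerance = size_tolerance,
                               min_share = min_share))
  msg(quiet, "[score] ", length(ancestral), " ancestral loci, ",
      sum(!mat$presence), " losses, ",
      sum(calls$category == "germline_gain"), " germline gains, ",
      sum(calls$category == "somatic"), " somatic peaks")
  invisible(list(matrix = mat, calls = calls, ancestral = ancestral,
                 files = paths))
}

#' Estimate rates and write summary tables
#'
#' Writes a loss-rate summary TSV (family, N sexual/asexual, high-loss
#' locus count, mean rate and SE per treatment, t, one-tailed p), an
#' observed-versus-expected losses TSV for high-loss loci, and a
#' per-lineage somatic-rate TSV.
#'
#' @param matrix_tsv Path to the matrix TSV, or a `presence_matrix`.
#' @param calls_csv Path to the calls CSV, or a calls data.frame.
#' @param lineages_tsv Path to lineage metadata TSV, or the data.frame.
#' @param out_dir Output directory.
#' @param family_id Family label for the summary row.
#' @param var_equal,tails Passed to [compare_treatments()].
#' @param high_loss_min Passed to [identify_high_loss_loci()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the rate summary, comparison,
#'   expected/observed table, per-lineage somatic rates and file paths.
#' @export
run_rates <- function(matrix_tsv, calls_csv, lineages_tsv, out_dir,
                      family_id = "TE1", var_equal = TRUE, tails = 1,
                      high_loss_min = 3, quiet = FALSE) {
  mat <- if (is.character(matrix_tsv)) read_presence_matrix(matrix_tsv) else
    matrix_tsv
  calls <- if (is.character(calls_csv)) read_peak_calls(calls_csv) else
    calls_csv
  meta <- if (is.character(lineages_tsv)) read_lineage_table(lineages_tsv)
    else lineages_tsv
  miss <- setdiff(rownames(mat$presence), meta$lineage_id)
  if (length(miss)) {
    stop("lineage(s) in matrix but not in metadata: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gens <- stats::setNames(meta$generations, meta$lineage_id)
  rs <- summarize_rates(mat, gens, high_loss_min)
  cmp <- compare_treatments(
    rs$rates$rate[rs$rates$treatment == "sexual"],
    rs$rates$rate[rs$rates$treatment == "asexual"],
    var_equal = var_equal, tails = tails)
  hl <- identify_high_loss_loci(mat, high_loss_min)
  k_bouts <- max(1L, round(stats::median(vapply(
    strsplit(meta$selfing_generations[meta$treatment == "sexual"], ","),
    function(x) sum(nzchar(x)), 0L))))
  evo <- expected_vs_observed_high_loss(mat, hl, n_selfing_bouts = k_bouts)
  som <- somatic_rates_per_lineage(calls)
  s_sex <- rs$summary[rs$summary$treatment == "sexual", ]
  s_asex <- rs$summary[rs$summary$treatment == "asexual", ]
  table2 <- data.frame(
    family = family_id,
    n_sexual = s_sex$n, n_asexual = s_asex$n,
    n_high_loss_loci = rs$n_high_loss_loci,
    rate_sexual = signif(s_sex$mean_rate, 4),
    se_sexual = signif(s_sex$se_rate, 4),
    rate_asexual = signif(s_asex$mean_rate, 4),
    se_asexual = signif(s_asex$se_rate, 4),
    t = signif(cmp$t_statistic, 4), p = signif(cmp$p_value, 4),
    stringsAsFactors = FALSE
  )
  paths <- file.path(out_dir, c("rate_summary.tsv", "expected_losses.tsv",
                                "somatic_rates.tsv"))
  utils::write.table(table2, paths[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(evo, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(som, paths[3], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_manifest(NULL, paths, file.path(out_dir, "rates_manifest.json"),
                 stage = "rates",
                 params = list(t_test = if (var_equal) "pooled" else "welch",
                               tails = tails, high_loss_min = high_loss_min))
  msg(quiet, "[rates] sexual ", signif(s_sex$mean_rate, 3), " vs asexual ",
      signif(s_asex$mean_rate, 3), " (t = ", signif(cmp$t_statistic, 3),
      ", p = ", signif(cmp$p_value, 3), ")")
  invisible(list(rate_summary = rs, comparison = cmp, table2 = table2,
                 expected_observed = evo, somatic = som, files = paths))
}

#' Per-lineage somatic gain rates from peak calls
#'
#' @param calls Output of [classify_new_peaks()].
#' @return Data.frame with `lineage_id`, `n_somatic`, `n_ancestral`,
#'   `somatic_rate` (lineages with zero ancestral peaks are dropped, the
#'   rate being undefined for them).
#' @export
somatic_rates_per_lineage <- function(calls) {
  ids <- unique(calls$lineage_id)
  n_som <- vapply(ids, function(id)
    sum(calls$lineage_id == id & calls$category == "somatic"), 0L)
  n_anc <- vapply(ids, function(id)
    sum(calls$lineage_id == id & calls$category == "ancestral"), 0L)
  keep <- n_anc >= 1L
  data.frame(lineage_id = ids[keep], n_somatic = n_som[keep],
             n_ancestral = n_anc[keep],
             somatic_rate = n_som[keep] / n_anc[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full pipeline: simulate, score, estimate rates
#'
#' @param config A [sim_config()] or YAML path.
#' @param out_dir Output directory (stages write into subdirectories
#'   `sim/`, `score/`, `rates/`).
#' @param seed Optional seed override.
#' @param ... Passed on to [run_score()] and [run_rates()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with each stage's results.
#' @export
run_all <- function(config, out_dir, seed = NULL, quiet = FALSE, ...) {
  if (is.character(config)) config <- read_sim_config(config)
  sim <- run_simulate(config, file.path(out_dir, "sim"), seed = seed,
                      quiet = quiet)
  dots <- list(...)
  score_args <- dots[names(dots) %in%
                       c("height_threshold", "size_tolerance", "min_share")]
  sc <- do.call(run_score, c(list(
    peaks_csv = file.path(out_dir, "sim", "peaks.csv"),
    lineages_tsv = file.path(out_dir, "sim", "lineages.tsv"),
    out_dir = file.path(out_dir, "score"), quiet = quiet),
    if (is.null(score_args$height_threshold))
      list(height_threshold = sim$config$height_threshold) else NULL,
    score_args))
  rate_args <- dots[names(dots) %in% c("var_equal", "tails", "high_loss_min")]
  rt <- do.call(run_rates, c(list(
    matrix_tsv = file.path(out_dir, "score", "matrix.tsv"),
    calls_csv = file.path(out_dir, "score", "calls.csv"),
    lineages_tsv = file.path(out_dir, "sim", "lineages.tsv"),
    out_dir = file.path(out_dir, "rates"),
    family_id = sim$config$family_id, quiet = quiet),
    rate_args))
  invisible(list(sim = sim, score = sc, rates = rt))
}
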