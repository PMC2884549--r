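# Simulation configuration: the study conditions of the MA experiment
# (cohort sizes, generations, ancestral genotype mix, event rates, TD
# emulation parameters) plus the RNG seed that fully determines a cohort.

#' Simulation configuration for an MA cohort
#'
#' Defaults reproduce the design of the mutation-accumulation experiment:
#' 94 lines (47 propagated strictly clonally, 47 with at least one bout of
#' selfing) run for ~40 generations, assayed once at the end by triplicate
#' transposon display.
#'
#' @param n_asexual Number of strictly clonal lines.
#' @param n_sexual Number of lines with selfing bout(s).
#' @param generations_mean Mean generations per line.
#' @param generations_sd SD of per-line generation counts (0 = all lines
#'   run exactly `generations_mean` generations).
#' @param n_ancestral_loci Ancestrally occupied TD loci for this TE family.
#' @param fraction_heterozygous Fraction of ancestral loci heterozygous in
#'   the single founding individual; the remainder are homozygous.
#' @param excision_rate Per-copy per-generation probability of local loss
#'   (excision, deletion or mitotic recombination, pooled).
#' @param reconstitution_prob Probability that an excised copy at a
#'   homozygous locus is restored by homologue-templated DNA repair.
#' @param germline_transposition_rate Per-element per-generation
#'   probability of a new heterozygous insertion at a fresh locus.
#' @param somatic_rate Expected somatic peaks per occupied locus at assay.
#' @param somatic_replicate_detection Probability a somatic peak is seen
#'   in any one TD replicate.
#' @param selfing_generation Generation of the (first) selfing bout in
#'   sexual lines; default is the mid-experiment generation.
#' @param n_selfings Selfing bouts per sexual line.
#' @param fragment_size_range Inclusive bp range of TD fragment sizes
#'   (the fragment-analysis sizing window).
#' @param seed Integer RNG seed; one seed determines the whole cohort.
#' @param family_id Label for the TE family being simulated.
#' @param height_meanlog_germline,height_meanlog_somatic,height_sdlog
#'   Log-normal parameters of peak heights (germline peaks are taller
#'   than somatic ones on average).
#' @param height_threshold Scoring height threshold calibrated so that no
#'   true peak from the default height distributions is discarded.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_asexual = 47,
                       n_sexual = 47,
                       generations_mean = 40,
                       generations_sd = 0,
                       n_ancestral_loci = 25,
                       fraction_heterozygous = 0.2,
                       excision_rate = 1e-4,
                       reconstitution_prob = 1,
                       germline_transposition_rate = 1e-5,
                       somatic_rate = 0.05,
                       somatic_replicate_detection = 0.4,
                       selfing_generation = NULL,
                       n_selfings = 1,
                       fragment_size_range = c(60, 1200),
                       seed = 1,
                       family_id = "TE1",
                       height_meanlog_germline = 7.6,
                       height_meanlog_somatic = 6.4,
                       height_sdlog = 0.35,
                       height_threshold = 50) {
  cfg <- list(
    n_asexual = n_asexual, n_sexual = n_sexual,
    generations_mean = generations_mean, generations_sd = generations_sd,
    n_ancestral_loci = n_ancestral_loci,
    fraction_heterozygous = fraction_heterozygous,
    excision_rate = excision_rate,
    reconstitution_prob = reconstitution_prob,
    germline_transposition_rate = germline_transposition_rate,
    somatic_rate = somatic_rate,
    somatic_replicate_detection = somatic_replicate_detection,
    selfing_generation = if (is.null(selfing_generation))
      max(1L, round(generations_mean / 2)) else selfing_generation,
    n_selfings = n_selfings,
    fragment_size_range = fragment_size_range,
    seed = seed, family_id = family_id,
    height_meanlog_germline = height_meanlog_germline,
    height_meanlog_somatic = height_meanlog_somatic,
    height_sdlog = height_sdlog,
    height_threshold = height_threshold
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, name, min = 0) {
    if (length(x) != 1L || is.na(x) || x < min || x != round(x)) {
      stop("config field '", name, "' must be an integer >= ", min,
           ", got: ", x, call. = FALSE)
    }
  }
  chk_prob <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("config field '", name, "' must be a probability in [0, 1], got: ",
           x, call. = FALSE)
    }
  }
  chk_count(cfg$n_asexual, "n_asexual")
  chk_count(cfg$n_sexual, "n_sexual")
  chk_count(cfg$generations_mean, "generations_mean", min = 1)
  if (cfg$generations_sd < 0) stop("generations_sd must be >= 0", call. = FALSE)
  chk_count(cfg$n_ancestral_loci, "n_ancestral_loci", min = 1)
  chk_prob(cfg$fraction_heterozygous, "fraction_heterozygous")
  chk_prob(cfg$excision_rate, "excision_rate")
  chk_prob(cfg$reconstitution_prob, "reconstitution_prob")
  chk_prob(cfg$germline_transposition_rate, "germline_transposition_rate")
  if (cfg$somatic_rate < 0) stop("somatic_rate must be >= 0", call. = FALSE)
  chk_prob(cfg$somatic_replicate_detection, "somatic_replicate_detection")
  chk_count(cfg$selfing_generation, "selfing_generation", min = 1)
  chk_count(cfg$n_selfings, "n_selfings", min = 0)
  if (length(cfg$fragment_size_range) != 2L ||
      any(cfg$fragment_size_range != round(cfg$fragment_size_range)) ||
      cfg$fragment_size_range[1] >= cfg$fragment_size_range[2] ||
      cfg$fragment_size_range[1] < 1) {
    stop("fragment_size_range must be two increasing positive integers (bp)",
         call. = FALSE)
  }
  chk_count(cfg$seed, "seed")
  if (cfg$height_sdlog <= 0) stop("height_sdlog must be > 0", call. = FALSE)
  if (cfg$height_threshold < 0) stop("height_threshold must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Every field of [sim_config()] is addressable by name; unknown keys are
#' an error (typo protection for reproducible runs).
#'
#' @param path Path to a YAML key-value file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(known, collapse = ", "), call. = FALSE)
  }
  if (!is.null(vals$fragment_size_range)) {
    vals$fragment_size_range <- as.numeric(unlist(vals$fragment_size_range))
  }
  do.call(sim_config, vals)
}

#' Write a simulation configuration to YAML
#'
#' @param config A `sim_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("MA simulation config (family ", x$family_id, "):\n", sep = "")
  cat("  lines: ", x$n_asexual, " asexual + ", x$n_sexual, " sexual, ",
      x$generations_mean, " generations (sd ", x$generations_sd, ")\n", sep = "")
  cat("  loci: ", x$n_ancestral_loci, " ancestral (",
      round(100 * x$fraction_heterozygous), "% het), sizes ",
      x$fragment_size_range[1], "-", x$fragment_size_range[2], " bp\n", sep = "")
  cat("  rates: excision ", x$excision_rate, ", transposition ",
      x$germline_transposition_rate, ", somatic ", x$somatic_rate,
      "/locus\n", sep = "")
  cat("  selfing: ", x$n_selfings, " bout(s), first at generation ",
      x$selfing_generation, "\n  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
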