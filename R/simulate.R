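# Forward simulation of the MA experiment: a single founding genotype,
# clonal propagation with rare excision / transposition, selfing bouts in
# the sexual treatment, and (in td_emulate.R) triplicate transposon-
# display peak tables at the assay endpoint.

EVENT_TYPES <- c("segregational_loss", "excision_loss", "reconstitution",
                 "germline_gain", "somatic_peak")

# deterministic per-lineage RNG sub-stream derived from (seed, index);
# kept below 2^31 - 1 (R integer range)
lineage_seed <- function(seed, i, stage = 0L) {
  as.integer((as.numeric(seed) %% 100000) * 20011 + i * 7919 +
               stage * 500009) %% 2147483647L
}

# prebuilt once: data.frame() construction is too slow for the
# per-lineage hot path
.empty_events <- data.frame(generation = integer(), locus_id = character(),
                            event = character(), stringsAsFactors = FALSE)

empty_event_log <- function() .empty_events

log_events <- function(line, locus_ids, event) {
  if (!length(locus_ids)) return(line)
  line$events <- rbind(line$events, data.frame(
    generation = line$generation, locus_id = locus_ids,
    event = event, stringsAsFactors = FALSE))
  line
}

#' Construct a lineage record
#'
#' One MA line: its treatment, target generation count, selfing schedule,
#' current per-locus genotypes and event log.
#'
#' @param lineage_id Identifier.
#' @param treatment `"sexual"` or `"asexual"`.
#' @param generations Total generations this line is propagated.
#' @param selfing_generations Generation indices of selfing bouts (must be
#'   empty for asexual lines).
#' @param loci Locus data.frame as built by [init_ancestor()].
#' @return A list of class `ma_lineage`.
#' @export
new_lineage <- function(lineage_id, treatment, generations,
                        selfing_generations, loci) {
  treatment <- match.arg(treatment, c("sexual", "asexual"))
  if (treatment == "asexual" && length(selfing_generations)) {
    stop("asexual lines must have an empty selfing schedule", call. = FALSE)
  }
  structure(list(
    lineage_id = lineage_id, treatment = treatment,
    generations = as.integer(generations), generation = 0L,
    selfing_generations = as.integer(selfing_generations),
    loci = loci, events = empty_event_log()
  ), class = "ma_lineage")
}

#' @export
print.ma_lineage <- function(x, ...) {
  cat("MA lineage ", x$lineage_id, " (", x$treatment, "), generation ",
      x$generation, "/", x$generations, "\n", sep = "")
  occ <- sum(x$loci$copies >= 1L)
  cat("  loci: ", nrow(x$loci), " (", occ, " occupied), events logged: ",
      nrow(x$events), "\n", sep = "")
  invisible(x)
}

#' Build the ancestral locus set
#'
#' Draws `n_ancestral_loci` loci with unique integer TD fragment sizes in
#' the configured range; `round(fraction_heterozygous * n)` of them are
#' heterozygous in the founder, the remainder homozygous. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `locus_id`, `fragment_bp`, `copies`,
#'   `origin`.
#' @export
init_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sizes_avail <- seq(config$fragment_size_range[1], config$fragment_size_range[2])
  n <- config$n_ancestral_loci
  if (n > length(sizes_avail)) {
    stop("n_ancestral_loci (", n, ") exceeds the number of distinct fragment ",
         "sizes in range (", length(sizes_avail), ")", call. = FALSE)
  }
  set.seed(lineage_seed(config$seed, 0L))
  sizes <- sample(sizes_avail, n)
  n_het <- round(config$fraction_heterozygous * n)
  data.frame(
    locus_id = sprintf("L%03d", seq_len(n)),
    fragment_bp = as.integer(sizes),
    copies = c(rep(1L, n_het), rep(2L, n - n_het)),
    origin = "ancestral",
    stringsAsFactors = FALSE
  )
}

# draw n new fragment sizes not colliding with `used` (exact-size scoring
# bins require uniqueness within a lineage)
draw_new_sizes <- function(n, range, used) {
  free <- setdiff(seq(range[1], range[2]), used)
  if (length(free) < n) {
    stop("no free fragment sizes left for new insertions", call. = FALSE)
  }
  if (n == 1L) free[sample.int(length(free), 1L)] else sample(free, n)
}

#' Advance a lineage one clonal generation
#'
#' Each genomic copy independently excises with `excision_rate`. An
#' excised copy at a heterozygous locus leaves the locus empty
#' (`excision_loss`); at a homozygous locus the gap is repaired from the
#' intact homologue with `reconstitution_prob` (`reconstitution`),
#' otherwise the locus drops to one copy. If both copies of a homozygous
#' locus excise in the same generation no template remains and the locus
#' is lost. Each existing copy also seeds a new heterozygous insertion at
#' a fresh locus with `germline_transposition_rate` (`germline_gain`).
#'
#' @param line An `ma_lineage`.
#' @param config A [sim_config()].
#' @return The advanced lineage.
#' @export
propagate_clonal_generation <- function(line, config) {
  line$generation <- line$generation + 1L
  e <- config$excision_rate
  copies <- line$loci$copies
  if (e > 0) {
    het <- which(copies == 1L)
    if (length(het)) {
      lost <- het[stats::runif(length(het)) < e]
      if (length(lost)) {
        copies[lost] <- 0L
        line$loci$copies <- copies
        line <- log_events(line, line$loci$locus_id[lost], "excision_loss")
      }
    }
    hom <- which(copies == 2L)
    if (length(hom)) {
      # each excised copy is repaired from the homologue immediately
      # (double-strand-break repair within the cell cycle), so excisions
      # at one locus are resolved sequentially within a generation
      n_exc <- stats::rbinom(length(hom), 2L, e)
      hit <- which(n_exc > 0L)
      if (length(hit)) {
        n_fail <- stats::rbinom(length(hit), n_exc[hit],
                                1 - config$reconstitution_prob)
        restored <- hit[n_exc[hit] > n_fail]
        if (length(restored)) {
          line <- log_events(line, line$loci$locus_id[hom[restored]],
                             "reconstitution")
        }
        failed <- hit[n_fail > 0L]
        if (length(failed)) {
          copies[hom[failed]] <- 2L - n_fail[match(failed, hit)]
          line$loci$copies <- copies
          line <- log_events(line, line$loci$locus_id[hom[failed]],
                             "excision_loss")
        }
      }
    }
  }
  tr <- config$germline_transposition_rate
  if (tr > 0) {
    n_copies <- sum(line$loci$copies)
    if (n_copies > 0L) {
      n_new <- stats::rbinom(1L, n_copies, tr)
      if (n_new > 0L) {
        sizes <- draw_new_sizes(n_new, config$fragment_size_range,
                                line$loci$fragment_bp)
        ids <- sprintf("%s.g%d.n%d", line$lineage_id, line$generation,
                       seq_len(n_new))
        line$loci <- rbind(line$loci, data.frame(
          locus_id = ids, fragment_bp = as.integer(sizes),
          copies = 1L, origin = "germline_gain", stringsAsFactors = FALSE))
        line <- log_events(line, ids, "germline_gain")
      }
    }
  }
  line
}

#' Apply one bout of selfing to a sexual lineage
#'
#' Replaces that generation's clonal reproduction with self-fertilization:
#' every locus is independently resampled from its Mendelian offspring
#' distribution. Heterozygous loci become absent / het / hom with
#' probabilities 0.25 / 0.50 / 0.25; homozygous and absent loci are
#' unchanged. Losses are logged as `segregational_loss`.
#'
#' @param line A sexual `ma_lineage`.
#' @param config A [sim_config()] (unused rates; kept for a uniform
#'   propagation signature).
#' @return The selfed lineage, with its generation counter advanced.
#' @export
apply_selfing <- function(line, config = NULL) {
  if (!identical(line$treatment, "sexual")) {
    stop("apply_selfing() called on lineage '", line$lineage_id,
         "' with treatment '", line$treatment,
         "': only sexual lines undergo meiosis", call. = FALSE)
  }
  line$generation <- line$generation + 1L
  het <- which(line$loci$copies == 1L)
  if (length(het)) {
    draw <- sample(0:2, length(het), replace = TRUE,
                   prob = c(0.25, 0.5, 0.25))
    line$loci$copies[het] <- as.integer(draw)
    lost <- het[draw == 0L]
    if (length(lost)) {
      line <- log_events(line, line$loci$locus_id[lost], "segregational_loss")
    }
  }
  line
}

# selfing schedule for one sexual line
selfing_schedule <- function(config, generations) {
  k <- config$n_selfings
  if (k == 0L) return(integer())
  first <- min(config$selfing_generation, generations)
  if (k == 1L) return(as.integer(first))
  unique(as.integer(round(seq(first, generations, length.out = k))))
}

#' Simulate a full MA cohort
#'
#' All lines descend from one ancestor built by [init_ancestor()].
#' Asexual lines receive only clonal generations; sexual lines receive
#' clonal generations with selfing bouts at the configured generations.
#' A single seed fully determines the cohort: each lineage runs on its
#' own RNG sub-stream derived from `(seed, lineage index)`.
#'
#' @param config A [sim_config()].
#' @return A list of `ma_lineage` objects of class `ma_cohort`, with the
#'   ancestor and config attached as attributes.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ancestor <- init_ancestor(config)
  n_total <- config$n_asexual + config$n_sexual
  treatments <- rep(c("asexual", "sexual"),
                    c(config$n_asexual, config$n_sexual))
  ids <- sprintf("%s%03d", ifelse(treatments == "asexual", "A", "S"),
                 c(seq_len(config$n_asexual), seq_len(config$n_sexual)))
  lines <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(lineage_seed(config$seed, i))
    gens <- if (config$generations_sd > 0) {
      max(1L, as.integer(round(stats::rnorm(1, config$generations_mean,
                                            config$generations_sd))))
    } else {
      as.integer(config$generations_mean)
    }
    sched <- if (treatments[i] == "sexual") {
      selfing_schedule(config, gens)
    } else {
      integer()
    }
    line <- new_lineage(ids[i], treatments[i], gens, sched, ancestor)
    if (config$excision_rate == 0 &&
        config$germline_transposition_rate == 0) {
      # a clonal generation is then a pure counter increment (and
      # consumes no random numbers), so only selfing bouts need running
      for (sg in sched) {
        line$generation <- sg - 1L
        line <- apply_selfing(line, config)
      }
      line$generation <- gens
    } else {
      for (g in seq_len(gens)) {
        line <- if (g %in% sched) {
          apply_selfing(line, config)
        } else {
          propagate_clonal_generation(line, config)
        }
      }
    }
    lines[[i]] <- line
  }
  names(lines) <- ids
  structure(lines, class = "ma_cohort", ancestor = ancestor, config = config)
}

#' @export
print.ma_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  tr <- vapply(x, `[[`, "", "treatment")
  cat("MA cohort (family ", cfg$family_id, "): ", length(x), " lineages (",
      sum(tr == "asexual"), " asexual, ", sum(tr == "sexual"),
      " sexual), seed ", cfg$seed, "\n", sep = "")
  invisible(x)
}

#' Combined event log of a cohort
#'
#' @param cohort An `ma_cohort`.
#' @return A data.frame with columns `lineage_id`, `generation`,
#'   `locus_id`, `event` (one row per event).
#' @export
cohort_events <- function(cohort) {
  evs <- lapply(cohort, function(line) {
    if (!nrow(line$events)) return(NULL)
    cbind(lineage_id = line$lineage_id, line$events)
  })
  evs <- evs[!vapply(evs, is.null, logical(1))]
  if (!length(evs)) {
    return(data.frame(lineage_id = character(), generation = integer(),
                      locus_id = character(), event = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, evs)
  rownames(out) <- NULL
  out
}

#' Per-lineage metadata table of a cohort
#'
#' @param cohort An `ma_cohort`.
#' @return A data.frame with `lineage_id`, `treatment`, `generations`,
#'   `selfing_generations` (comma-joined).
#' @export
cohort_metadata <- function(cohort) {
  data.frame(
    lineage_id = vapply(cohort, `[[`, "", "lineage_id"),
    treatment = vapply(cohort, `[[`, "", "treatment"),
    generations = vapply(cohort, `[[`, 0L, "generations"),
    selfing_generations = vapply(cohort, function(l)
      paste(l$selfing_generations, collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
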