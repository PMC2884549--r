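# Rate estimation and treatment comparison: losses per lineage per
# generation per ancestral element copy, germline transposition and
# somatic gain rates, pooled t-tests between treatments, ANCOVA across
# families with ancestral copy number as covariate, and OLS of somatic
# rate on family copy number.

#' Loss rate for one lineage
#'
#' Losses per lineage per generation per ancestral element copy.
#'
#' @param losses Number of absent ancestral entries in the lineage's row.
#' @param generations Generations of mutation accumulation for the line.
#' @param ancestral_copies Ancestral element copies assayed (the number
#'   of ancestral TD loci).
#' @return A single non-negative rate.
#' @examples
#' loss_rate_per_lineage(2, 40, 25)  # 0.002
#' @export
loss_rate_per_lineage <- function(losses, generations, ancestral_copies) {
  if (length(generations) != 1L || is.na(generations) || generations < 1) {
    stop("generations must be >= 1", call. = FALSE)
  }
  if (length(ancestral_copies) != 1L || is.na(ancestral_copies) ||
      ancestral_copies < 1) {
    stop("ancestral_copies must be >= 1", call. = FALSE)
  }
  if (losses < 0) stop("losses must be >= 0", call. = FALSE)
  losses / (generations * ancestral_copies)
}

#' Summarize loss rates per treatment
#'
#' Computes each lineage's loss rate (losses in its matrix row, divided
#' by its generation count and the number of ancestral loci) and
#' aggregates to per-treatment mean and standard error (sample SD across
#' lineages / sqrt(n), the MA-experiment convention).
#'
#' @param matrix A `presence_matrix`.
#' @param generations Single generation count applied to all lineages, or
#'   a named vector (names = lineage ids).
#' @param high_loss_min Threshold passed to [identify_high_loss_loci()].
#' @return A list of class `rate_summary`: `rates` (per-lineage
#'   data.frame), `summary` (per-treatment data.frame with `n`,
#'   `mean_rate`, `se_rate`), `n_high_loss_loci`, `n_ancestral_loci`.
#' @export
summarize_rates <- function(matrix, generations, high_loss_min = 3) {
  stopifnot(inherits(matrix, "presence_matrix"))
  ids <- rownames(matrix$presence)
  gens <- if (length(generations) == 1L && is.null(names(generations))) {
    stats::setNames(rep(as.numeric(generations), length(ids)), ids)
  } else {
    miss <- setdiff(ids, names(generations))
    if (length(miss)) {
      stop("generations missing for lineage(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    as.numeric(generations[ids])
  }
  n_loci <- ncol(matrix$presence)
  losses <- rowSums(!matrix$presence)
  rates <- vapply(seq_along(ids), function(i)
    loss_rate_per_lineage(losses[i], gens[i], n_loci), 0)
  per_lineage <- data.frame(
    lineage_id = ids, treatment = matrix$treatment[ids],
    losses = as.integer(losses), generations = gens,
    rate = rates, stringsAsFactors = FALSE, row.names = NULL
  )
  tr_levels <- c("sexual", "asexual")
  empty <- setdiff(tr_levels, unique(per_lineage$treatment))
  if (length(empty)) {
    stop("treatment(s) with zero lineages: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  summ <- do.call(rbind, lapply(tr_levels, function(tr) {
    r <- per_lineage$rate[per_lineage$treatment == tr]
    data.frame(treatment = tr, n = length(r), mean_rate = mean(r),
               se_rate = if (length(r) > 1L)
                 stats::sd(r) / sqrt(length(r)) else 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(rates = per_lineage, summary = summ,
                 n_high_loss_loci =
                   length(identify_high_loss_loci(matrix, high_loss_min)),
                 n_ancestral_loci = n_loci),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("Loss rates per ancestral insertion per generation (",
      x$n_ancestral_loci, " ancestral loci, ", x$n_high_loss_loci,
      " high-loss):\n", sep = "")
  print(x$summary, row.names = FALSE, ...)
  invisible(x)
}

#' Germline transposition rate from observed gains
#'
#' Gains per ancestral element copy per line-generation: the observed
#' count of new replicable insertions divided by the product of the
#' ancestral copy number and the summed generations across all lines
#' surveyed.
#'
#' @param gains Number of germline gains observed cohort-wide.
#' @param ancestral_copies Ancestral element copies for the family.
#' @param total_line_generations Sum of generation counts across lines.
#' @return A single non-negative rate.
#' @examples
#' germline_gain_rate(1, 3, 94 * 40)  # ~8.9e-05
#' @export
germline_gain_rate <- function(gains, ancestral_copies,
                               total_line_generations) {
  if (ancestral_copies < 1 || total_line_generations < 1) {
    stop("denominators must be >= 1", call. = FALSE)
  }
  if (gains < 0) stop("gains must be >= 0", call. = FALSE)
  gains / (ancestral_copies * total_line_generations)
}

#' Somatic gain rate for one lineage
#'
#' New non-replicable peaks divided by ancestral peaks (per assay
#' endpoint; not per generation).
#'
#' @param n_somatic_peaks Putative somatic peaks in the lineage.
#' @param n_ancestral_peaks Ancestral peaks present in the lineage.
#' @return A single non-negative rate.
#' @export
somatic_gain_rate <- function(n_somatic_peaks, n_ancestral_peaks) {
  if (length(n_ancestral_peaks) != 1L || n_ancestral_peaks < 1) {
    stop("n_ancestral_peaks must be >= 1", call. = FALSE)
  }
  if (n_somatic_peaks < 0) stop("n_somatic_peaks must be >= 0", call. = FALSE)
  n_somatic_peaks / n_ancestral_peaks
}

#' Compare per-lineage rates between treatments
#'
#' Student's pooled-variance two-sample t-test of sexual versus asexual
#' per-lineage rates, one-tailed by default (the direction — higher loss
#' under sex — is predicted a priori by independent assortment). Welch
#' and two-tailed variants are available by flag.
#'
#' @param rates_sexual,rates_asexual Per-lineage rates (length >= 2 each).
#' @param var_equal Pooled variance (`TRUE`, default) or Welch.
#' @param tails 1 (H1: sexual > asexual) or 2.
#' @param alpha Significance level used only to label `direction`.
#' @return A list of class `comparison_result`: `t_statistic`, `df`,
#'   `p_value`, `direction` (`"sexual_greater"`, `"asexual_greater"` or
#'   `"none"`), `method`, `tails`.
#' @export
compare_treatments <- function(rates_sexual, rates_asexual,
                               var_equal = TRUE, tails = 1, alpha = 0.05) {
  if (length(rates_sexual) < 2L || length(rates_asexual) < 2L) {
    stop("need at least 2 lineages per treatment (variance undefined ",
         "otherwise)", call. = FALSE)
  }
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2", call. = FALSE)
  alt <- if (tails == 1) "greater" else "two.sided"
  if (stats::var(rates_sexual) == 0 && stats::var(rates_asexual) == 0) {
    # both treatments internally constant (e.g. no losses anywhere):
    # define the comparison by its limit rather than erroring out
    d <- mean(rates_sexual) - mean(rates_asexual)
    t_stat <- if (d == 0) 0 else sign(d) * Inf
    df <- length(rates_sexual) + length(rates_asexual) - 2
    p <- if (tails == 1) {
      stats::pt(t_stat, df, lower.tail = FALSE)
    } else {
      2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
    }
  } else {
    tt <- stats::t.test(rates_sexual, rates_asexual, alternative = alt,
                        var.equal = var_equal)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  direction <- if (p < alpha) {
    if (t_stat > 0) "sexual_greater" else "asexual_greater"
  } else {
    "none"
  }
  structure(list(t_statistic = t_stat, df = df,
                 p_value = p, direction = direction,
                 method = if (var_equal) "pooled" else "welch",
                 tails = tails),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("t = %.3g, df = %.4g, %s-tailed p = %.3g (%s variance); %s\n",
              x$t_statistic, x$df, x$tails, x$p_value, x$method,
              x$direction))
  invisible(x)
}

#' Regress somatic gain rate on family copy number
#'
#' Ordinary least squares of per-family mean somatic rate on ancestral
#' copy number (untransformed by default; `log_copy_number` fits against
#' log10 copies since the scale is not dictated by the data).
#'
#' @param family_means Data.frame with columns `copy_number` and
#'   `somatic_rate` (>= 3 rows).
#' @param log_copy_number Regress on log10(copy number) instead.
#' @return A list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `df_model`, `df_residual`, `p_value`.
#' @export
regress_somatic_vs_copy_number <- function(family_means,
                                           log_copy_number = FALSE) {
  req <- c("copy_number", "somatic_rate")
  if (!all(req %in% names(family_means))) {
    stop("family_means must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(family_means) < 3L) {
    stop("need at least 3 family points for regression", call. = FALSE)
  }
  x <- if (log_copy_number) log10(family_means$copy_number) else
    family_means$copy_number
  y <- family_means$somatic_rate
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  df_res <- fit$df.residual
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    # constant response: nothing to explain
    r2 <- 0; f_stat <- 0; p <- 1
  } else {
    ss_res <- sum(stats::residuals(fit)^2)
    r2 <- 1 - ss_res / ss_tot
    f_stat <- if (ss_res == 0) Inf else (ss_tot - ss_res) / (ss_res / df_res)
    p <- stats::pf(f_stat, 1, df_res, lower.tail = FALSE)
  }
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r2, f_statistic = f_stat, df_model = 1L,
                 df_residual = df_res, p_value = p),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "OLS: slope = %.4g, R^2 = %.3g, F(%d, %d) = %.4g, p = %.3g\n",
    x$slope, x$r_squared, x$df_model, x$df_residual, x$f_statistic,
    x$p_value))
  invisible(x)
}

#' ANCOVA of loss rates across families
#'
#' Linear-model decomposition `rate ~ treatment + copy_number` (sequential
#' sums of squares), with ancestral copy number as the covariate;
#' optionally with the treatment x copy-number interaction.
#'
#' @param data Data.frame with columns `rate`, `treatment`, `family`,
#'   `copy_number` (one row per lineage).
#' @param interaction Include `treatment:copy_number`.
#' @return Data.frame with one row per model term: `term`, `df`,
#'   `sum_sq`, `f_statistic`, `p_value`.
#' @export
ancova_rates <- function(data, interaction = FALSE) {
  req <- c("rate", "treatment", "family", "copy_number")
  if (!all(req %in% names(data))) {
    stop("data must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(data$family)) < 2L) {
    stop("ANCOVA across families requires at least 2 families", call. = FALSE)
  }
  if (!all(c("sexual", "asexual") %in% data$treatment)) {
    stop("both treatments must be present", call. = FALSE)
  }
  form <- if (interaction) {
    rate ~ treatment + copy_number + treatment:copy_number
  } else {
    rate ~ treatment + copy_number
  }
  fit <- stats::lm(form, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design: a model term is confounded with the ",
         "others (e.g. copy_number constant, or identical across ",
         "treatments); drop or vary the offending covariate", call. = FALSE)
  }
  if (stats::var(data$rate) == 0) {
    terms <- attr(stats::terms(fit), "term.labels")
    return(data.frame(term = terms,
                      df = vapply(terms, function(t) 1L, 1L),
                      sum_sq = 0, f_statistic = 0, p_value = 1,
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  an <- stats::anova(fit)
  keep <- rownames(an) != "Residuals"
  data.frame(term = rownames(an)[keep], df = an$Df[keep],
             sum_sq = an$`Sum Sq`[keep], f_statistic = an$`F value`[keep],
             p_value = an$`Pr(>F)`[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Observed versus expected losses at high-loss loci
#'
#' For each high-loss locus, compares the number of sexual lineages that
#' lost it with the count expected if the locus was heterozygous in the
#' ancestor and assorted independently during the selfing bout(s):
#' `n_sexual x p_loss(k bouts)`. Loci exceeding the expectation are
#' flagged — the signature of local removal (excision, deletion, mitotic
#' recombination) acting on top of chromosomal segregation.
#'
#' @param matrix A `presence_matrix`.
#' @param high_loss_loci Fragment sizes
#'   (from [identify_high_loss_loci()]).
#' @param n_selfing_bouts Selfing bouts per sexual line.
#' @return Data.frame with columns `locus`, `observed`, `expected`,
#'   `exceeds_expectation`.
#' @export
expected_vs_observed_high_loss <- function(matrix, high_loss_loci,
                                           n_selfing_bouts = 1) {
  stopifnot(inherits(matrix, "presence_matrix"))
  sex_ids <- names(matrix$treatment)[matrix$treatment == "sexual"]
  n_sex <- length(sex_ids)
  p_loss <- unname(state_after_k_selfings(1, n_selfing_bouts)["p_absent"])
  expected <- expected_segregational_losses(n_sex, p_loss)
  loci <- as.character(high_loss_loci)
  observed <- if (n_sex && length(loci)) {
    colSums(!matrix$presence[sex_ids, loci, drop = FALSE])
  } else {
    rep(0, length(loci))
  }
  data.frame(locus = as.integer(loci), observed = as.numeric(observed),
             expected = rep(expected, length(loci)),
             exceeds_expectation = as.numeric(observed) > expected,
             stringsAsFactors = FALSE, row.names = NULL)
}
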