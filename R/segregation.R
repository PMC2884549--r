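# Closed-form Mendelian expectations for the fate of a single diploid
# insertion locus under clonal propagation, selfing and outcrossing.
# Genotypes are copy numbers at one locus: 0 (absent), 1 (heterozygous),
# 2 (homozygous). Loci are treated as unlinked and assort independently.

#' Validate a single-locus genotype
#'
#' @param genotype Copy number at one insertion locus; must be 0, 1 or 2.
#' @return The genotype as an integer scalar.
#' @keywords internal
validate_genotype <- function(genotype) {
  if (length(genotype) != 1L || !is.numeric(genotype) || is.na(genotype) ||
      !(genotype %in% c(0, 1, 2))) {
    stop("genotype must be a single value in {0, 1, 2} (copies at one locus), got: ",
         deparse(substitute(genotype)), " = ", paste(genotype, collapse = ","),
         call. = FALSE)
  }
  as.integer(genotype)
}

#' Construct an offspring genotype distribution
#'
#' A probability distribution over the three genotypes (absent,
#' heterozygous, homozygous) at a single insertion locus.
#'
#' @param p_absent,p_het,p_hom Probabilities of 0, 1 and 2 copies.
#' @return A named numeric vector of class `offspring_distribution` with
#'   elements `p_absent`, `p_het`, `p_hom`.
#' @export
offspring_distribution <- function(p_absent, p_het, p_hom) {
  p <- c(p_absent = p_absent, p_het = p_het, p_hom = p_hom)
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("probabilities must sum to 1 (tolerance 1e-12), got ", sum(p),
         call. = FALSE)
  }
  structure(p, class = "offspring_distribution")
}

#' @export
print.offspring_distribution <- function(x, ...) {
  cat("Offspring genotype distribution (absent / het / hom):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Offspring genotype distribution under one bout of selfing
#'
#' For a self-fertilized diploid, a heterozygous insertion segregates by
#' independent assortment: the offspring is absent / heterozygous /
#' homozygous with probabilities 1/4, 1/2, 1/4. Homozygous and absent
#' loci are invariant under selfing.
#'
#' @param genotype Parental copy number at the locus (0, 1 or 2).
#' @return An [offspring_distribution()].
#' @examples
#' selfing_offspring_distribution(1)  # 0.25 / 0.50 / 0.25
#' @export
selfing_offspring_distribution <- function(genotype) {
  g <- validate_genotype(genotype)
  switch(g + 1L,
    offspring_distribution(1, 0, 0),
    offspring_distribution(0.25, 0.5, 0.25),
    offspring_distribution(0, 0, 1)
  )
}

#' Probability of segregational loss of an insertion in one generation
#'
#' Probability that the offspring carries 0 copies at the locus, by
#' meiotic segregation alone (excision is modelled separately, in the
#' simulator). Under clonal reproduction there is no meiosis and hence no
#' segregational loss; under selfing a heterozygote is lost 25% of the
#' time; under outcrossing to a partner unoccupied at the locus, half of
#' a heterozygote's offspring inherit no copy.
#'
#' @param genotype Parental copy number at the locus (0, 1 or 2).
#' @param mode Reproductive mode: `"clonal"`, `"selfing"` or
#'   `"outcross_to_unoccupied"`.
#' @return A single probability.
#' @examples
#' loss_probability(1, "selfing")                 # 0.25
#' loss_probability(1, "outcross_to_unoccupied")  # 0.5
#' @export
loss_probability <- function(genotype,
                             mode = c("clonal", "selfing",
                                      "outcross_to_unoccupied")) {
  g <- validate_genotype(genotype)
  mode <- match.arg(mode)
  switch(mode,
    clonal = as.numeric(g == 0L),
    selfing = unname(selfing_offspring_distribution(g)["p_absent"]),
    # parental gamete carries the insertion with prob g/2; partner gametes
    # never do, so offspring has 0 copies iff the parental gamete is empty
    outcross_to_unoccupied = 1 - g / 2
  )
}

#' Transition matrix of the single-locus selfing Markov chain
#'
#' Rows and columns index genotypes 0, 1, 2. States 0 and 2 are absorbing.
#'
#' @return A 3x3 stochastic matrix.
#' @export
selfing_transition_matrix <- function() {
  matrix(c(1, 0, 0,
           0.25, 0.5, 0.25,
           0, 0, 1),
         nrow = 3, byrow = TRUE,
         dimnames = list(from = c("0", "1", "2"), to = c("0", "1", "2")))
}

#' Genotype distribution after k bouts of selfing
#'
#' Iterates the selfing Markov chain k steps from a given starting
#' genotype. A heterozygote halves its heterozygosity each bout:
#' `p_het = (1/2)^k`, with the remainder split equally between loss and
#' fixation. Supports sexual sublines that underwent more than one bout
#' of sex.
#'
#' @param genotype Starting copy number at the locus (0, 1 or 2).
#' @param k Number of selfing bouts (non-negative integer).
#' @return An [offspring_distribution()].
#' @examples
#' state_after_k_selfings(1, 2)  # 0.375 / 0.25 / 0.375
#' @export
state_after_k_selfings <- function(genotype, k) {
  g <- validate_genotype(genotype)
  if (length(k) != 1L || is.na(k) || k < 0 || k != round(k)) {
    stop("k must be a single non-negative integer, got ", k, call. = FALSE)
  }
  v <- numeric(3)
  v[g + 1L] <- 1
  P <- selfing_transition_matrix()
  for (i in seq_len(k)) v <- drop(v %*% P)
  v <- unname(v)
  offspring_distribution(v[1], v[2], v[3])
}

#' Expected number of segregational losses across lineages
#'
#' With `n_lineages` independent lines each losing a heterozygous locus
#' with probability `p_loss`, the expected number of observed losses is
#' their product: e.g. 45 selfed lines at the Mendelian 0.25 give 11.25
#' expected losses at an ancestrally heterozygous locus.
#'
#' @param n_lineages Number of lineages assayed (non-negative).
#' @param p_loss Per-lineage loss probability in \[0, 1\].
#' @return Expected count of losses.
#' @examples
#' expected_segregational_losses(45, 0.25)  # 11.25
#' @export
expected_segregational_losses <- function(n_lineages, p_loss) {
  if (length(n_lineages) != 1L || is.na(n_lineages) || n_lineages < 0) {
    stop("n_lineages must be a single non-negative number", call. = FALSE)
  }
  if (length(p_loss) != 1L || is.na(p_loss) || p_loss < 0 || p_loss > 1) {
    stop("p_loss must be a single probability in [0, 1]", call. = FALSE)
  }
  n_lineages * p_loss
}
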