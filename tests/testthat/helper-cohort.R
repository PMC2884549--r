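# Small cohort configurations used across tests; kept deliberately tiny
# so the default test run stays fast.

quiet_config <- function(...) {
  defaults <- list(n_asexual = 6, n_sexual = 6, generations_mean = 10,
                   n_ancestral_loci = 10, fraction_heterozygous = 0.2,
                   excision_rate = 0, germline_transposition_rate = 0,
                   somatic_rate = 0, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# a single lineage carrying the given genotype vector, for direct calls
# to the propagation operators
toy_lineage <- function(copies, treatment = "asexual",
                        selfing_generations = integer()) {
  loci <- data.frame(
    locus_id = sprintf("L%03d", seq_along(copies)),
    fragment_bp = as.integer(100 + 10 * seq_along(copies)),
    copies = as.integer(copies),
    origin = "ancestral", stringsAsFactors = FALSE)
  new_lineage("T001", treatment, 10L, selfing_generations, loci)
}
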