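# Forward MA simulator: ancestor construction, clonal propagation with
# excision / reconstitution / transposition, selfing, and cohort-level
# invariants.

test_that("ancestor has the configured het/hom mix and unique sizes", {
  cfg <- quiet_config(n_ancestral_loci = 20, fraction_heterozygous = 0.2)
  anc <- init_ancestor(cfg)
  expect_identical(nrow(anc), 20L)
  expect_identical(sum(anc$copies == 1L), 4L)
  expect_identical(sum(anc$copies == 2L), 16L)
  expect_false(anyDuplicated(anc$fragment_bp) > 0)
  expect_true(all(anc$fragment_bp >= 60 & anc$fragment_bp <= 1200))

  one <- init_ancestor(quiet_config(n_ancestral_loci = 1,
                                    fraction_heterozygous = 0))
  expect_identical(one$copies, 2L)

  expect_identical(init_ancestor(cfg), anc)  # same seed, same ancestor
  cfg2 <- quiet_config(n_ancestral_loci = 20, seed = 43)
  expect_false(identical(init_ancestor(cfg2)$fragment_bp, anc$fragment_bp))

  expect_error(init_ancestor(quiet_config(n_ancestral_loci = 50,
                                          fragment_size_range = c(60, 80))),
               "exceeds")
})

test_that("clonal propagation applies excision, repair and gain rules", {
  cfg0 <- quiet_config()
  line <- toy_lineage(c(1, 2, 0))
  out <- propagate_clonal_generation(line, cfg0)
  expect_identical(out$generation, 1L)
  expect_identical(out$loci, line$loci)          # all rates zero
  expect_identical(nrow(out$events), 0L)

  # forced excision at a het locus empties it
  cfg_e <- quiet_config(excision_rate = 1, reconstitution_prob = 0)
  set.seed(1)
  out <- propagate_clonal_generation(toy_lineage(1), cfg_e)
  expect_identical(out$loci$copies, 0L)
  expect_identical(out$events$event, "excision_loss")

  # homologue-templated repair keeps a homozygote intact indefinitely
  cfg_r <- quiet_config(excision_rate = 1, reconstitution_prob = 1)
  line <- toy_lineage(2)
  set.seed(1)
  for (g in 1:5) line <- propagate_clonal_generation(line, cfg_r)
  expect_identical(line$loci$copies, 2L)
  expect_true(all(line$events$event == "reconstitution"))

  # without repair a homozygote is stripped copy by copy
  set.seed(1)
  line <- toy_lineage(2)
  for (g in 1:5) line <- propagate_clonal_generation(line, cfg_e)
  expect_identical(line$loci$copies, 0L)

  # forced transposition: every copy seeds a new heterozygous locus
  cfg_t <- quiet_config(germline_transposition_rate = 1)
  set.seed(1)
  out <- propagate_clonal_generation(toy_lineage(c(2, 1)), cfg_t)
  gains <- out$loci[out$loci$origin == "germline_gain", ]
  expect_identical(nrow(gains), 3L)              # one per existing copy
  expect_true(all(gains$copies == 1L))
  expect_false(anyDuplicated(out$loci$fragment_bp) > 0)
})

test_that("selfing resamples heterozygous loci Mendelianly", {
  expect_error(apply_selfing(toy_lineage(1, treatment = "asexual")),
               "only sexual lines")

  hom_line <- toy_lineage(c(2, 2, 0), treatment = "sexual",
                          selfing_generations = 5L)
  out <- apply_selfing(hom_line)
  expect_identical(out$loci$copies, c(2L, 2L, 0L))
  expect_identical(nrow(out$events), 0L)

  # single het locus: loss fraction within 4 binomial SDs of 0.25
  set.seed(99)
  n <- 10000
  line <- toy_lineage(1, treatment = "sexual", selfing_generations = 5L)
  draws <- vapply(seq_len(n), function(i)
    apply_selfing(line)$loci$copies, 0L)
  p_hat <- mean(draws == 0L)
  expect_lt(abs(p_hat - 0.25), 4 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(mean(draws == 1L) - 0.5), 4 * sqrt(0.5 * 0.5 / n))

  # two het loci segregate independently: joint frequencies match the
  # 9-cell product distribution (chi-square GOF at alpha = 0.01)
  set.seed(7)
  n <- 6000
  line2 <- toy_lineage(c(1, 1), treatment = "sexual",
                       selfing_generations = 5L)
  joint <- t(vapply(seq_len(n), function(i)
    apply_selfing(line2)$loci$copies, c(0L, 0L)))
  obs <- table(factor(joint[, 1], 0:2), factor(joint[, 2], 0:2))
  p_marg <- c(0.25, 0.5, 0.25)
  expected <- outer(p_marg, p_marg) * n
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.99, df = 8))
})

test_that("cohorts have the configured structure and are seed-reproducible", {
  cfg <- sim_config(seed = 11)  # full default design
  co <- run_experiment(cfg)
  expect_length(co, 94)
  tr <- vapply(co, `[[`, "", "treatment")
  expect_identical(sum(tr == "asexual"), 47L)
  expect_identical(sum(tr == "sexual"), 47L)
  expect_true(all(vapply(co, `[[`, 0L, "generations") == 40L))
  expect_true(all(vapply(co[tr == "asexual"], function(l)
    length(l$selfing_generations) == 0L, TRUE)))
  expect_true(all(vapply(co[tr == "sexual"], function(l)
    identical(l$selfing_generations, 20L), TRUE)))
  ev <- cohort_events(co)
  expect_true(all(ev$generation <= 40L))

  co2 <- run_experiment(cfg)
  expect_identical(co, co2)
  expect_identical(emulate_td(co, cfg), emulate_td(co2, cfg))

  co3 <- run_experiment(sim_config(seed = 12))
  expect_false(identical(cohort_events(co3), ev))

  # asexual-only cohort never sees segregational loss
  co4 <- run_experiment(quiet_config(n_sexual = 0, excision_rate = 1e-3))
  expect_false("segregational_loss" %in% cohort_events(co4)$event)
})

test_that("with no excision, losses hit only het loci in sexual lines", {
  cfg <- quiet_config(n_asexual = 15, n_sexual = 15, n_ancestral_loci = 12,
                      fraction_heterozygous = 0.5, seed = 5)
  co <- run_experiment(cfg)
  anc <- attr(co, "ancestor")
  for (line in co) {
    lost <- line$loci$locus_id[line$loci$copies == 0L]
    if (line$treatment == "asexual") {
      expect_length(lost, 0)
    } else {
      expect_true(all(lost %in% anc$locus_id[anc$copies == 1L]))
    }
  }
  ev <- cohort_events(co)
  expect_true(all(ev$event == "segregational_loss"))
})

test_that("per-locus losses across selfed lines are Binomial(n, 1/4)", {
  n_lines <- 20L
  n_cohorts <- 400L
  counts <- vapply(seq_len(n_cohorts), function(s) {
    cfg <- quiet_config(n_asexual = 0, n_sexual = n_lines,
                        n_ancestral_loci = 1, fraction_heterozygous = 1,
                        seed = 50000 + s)
    co <- run_experiment(cfg)
    sum(vapply(co, function(l) l$loci$copies[1] == 0L, TRUE))
  }, 0L)
  # chi-square GOF against Binomial(20, 0.25), tails lumped so every
  # bin expects >= 5 counts
  breaks <- c(-Inf, 2:8, Inf)
  obs <- table(cut(counts, breaks))
  p_bin <- dbinom(0:n_lines, n_lines, 0.25)
  exp_p <- c(sum(p_bin[1:3]), p_bin[4:9], sum(p_bin[10:(n_lines + 1)]))
  expected <- n_cohorts * exp_p
  expect_true(all(expected >= 5))
  chi2 <- sum((as.numeric(obs) - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.99, df = length(expected) - 1))
})

test_that("conservation: zero-rate asexual lines equal the ancestor", {
  cfg <- quiet_config(n_sexual = 0, n_asexual = 8)
  co <- run_experiment(cfg)
  anc <- attr(co, "ancestor")
  for (line in co) {
    expect_identical(line$loci, anc)
    expect_identical(line$generation, 10L)
  }
})

test_that("TD emulation shows presence, hides dosage, splits somatic", {
  # het and hom at the same ancestral locus produce identical patterns
  cfg <- quiet_config(n_asexual = 2, n_sexual = 0, n_ancestral_loci = 4,
                      fraction_heterozygous = 0.5)
  co <- run_experiment(cfg)
  pk <- emulate_td(co, cfg)
  pat <- function(id) unique(pk[pk$lineage_id == id,
                                c("replicate", "fragment_bp")])
  p1 <- pat(co[[1]]$lineage_id); p2 <- pat(co[[2]]$lineage_id)
  expect_identical(p1[order(p1$replicate, p1$fragment_bp), ]$fragment_bp,
                   p2[order(p2$replicate, p2$fragment_bp), ]$fragment_bp)
  expect_true(all(pk$height > 0))
  # every occupied locus appears in all 3 replicates
  tabs <- table(pk$lineage_id, pk$fragment_bp)
  expect_true(all(tabs %in% c(0L, 3L)))

  # a lost locus leaves no peak at its size in any replicate
  line <- co[[1]]
  line$loci$copies[1] <- 0L
  co_mod <- co; co_mod[[1]] <- line
  pk2 <- emulate_td(co_mod, cfg)
  expect_false(line$loci$fragment_bp[1] %in%
                 pk2$fragment_bp[pk2$lineage_id == line$lineage_id])

  # somatic peaks land in 1 or 2 replicates, never 3
  cfg_s <- quiet_config(n_asexual = 20, n_sexual = 0, somatic_rate = 0.5,
                        seed = 8)
  co_s <- run_experiment(cfg_s)
  pk_s <- emulate_td(co_s, cfg_s)
  truth <- attr(pk_s, "somatic_truth")
  expect_gt(nrow(truth), 0)
  for (i in seq_len(nrow(truth))) {
    n_rep <- sum(pk_s$lineage_id == truth$lineage_id[i] &
                   pk_s$fragment_bp == truth$fragment_bp[i])
    expect_true(n_rep >= 1L && n_rep <= 2L)
  }
})
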