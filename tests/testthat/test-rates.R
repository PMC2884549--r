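# Rate estimation and treatment statistics, checked against closed-form
# and brute-force oracles.

test_that("per-lineage loss rate is losses per generation per copy", {
  expect_identical(loss_rate_per_lineage(2, 40, 25), 0.002)
  expect_identical(loss_rate_per_lineage(0, 17, 9), 0)
  expect_identical(loss_rate_per_lineage(1, 40, 1), 0.025)
  expect_error(loss_rate_per_lineage(1, 0, 25), "generations")
  expect_error(loss_rate_per_lineage(1, 40, 0), "ancestral_copies")
})

test_that("rate summaries match a spreadsheet-style manual computation", {
  ids <- c("S1", "S2", "A1", "A2")
  treatments <- setNames(c("sexual", "sexual", "asexual", "asexual"), ids)
  m <- matrix(TRUE, 4, 5, dimnames = list(ids, c(100, 150, 200, 250, 300)))
  m["S1", 1:2] <- FALSE  # 2 losses
  m["S2", 1] <- FALSE    # 1 loss
  m["A1", 3] <- FALSE    # 1 loss
  pm <- structure(list(presence = m, treatment = treatments),
                  class = "presence_matrix")
  gens <- setNames(c(40, 38, 40, 41), ids)
  rs <- summarize_rates(pm, gens)
  manual <- c(2 / (40 * 5), 1 / (38 * 5), 1 / (40 * 5), 0 / (41 * 5))
  expect_equal(rs$rates$rate, manual, tolerance = 1e-15)
  s_sex <- rs$summary[rs$summary$treatment == "sexual", ]
  expect_equal(s_sex$mean_rate, mean(manual[1:2]), tolerance = 1e-15)
  expect_equal(s_sex$se_rate, sd(manual[1:2]) / sqrt(2), tolerance = 1e-15)
  expect_identical(rs$n_high_loss_loci, 0L)

  # all-present matrix: zero rates, zero SEs, for both treatments
  pm$presence[] <- TRUE
  rs0 <- summarize_rates(pm, 40)
  expect_true(all(rs0$summary$mean_rate == 0))
  expect_true(all(rs0$summary$se_rate == 0))

  # identical per-lineage rates within a treatment give SE 0
  pm$presence[, 1] <- FALSE
  rs1 <- summarize_rates(pm, 40)
  expect_true(all(rs1$summary$se_rate == 0))
  expect_true(all(rs1$summary$mean_rate == 1 / (40 * 5)))

  pm_one <- structure(list(presence = m[1:2, ], treatment = treatments[1:2]),
                      class = "presence_matrix")
  expect_error(summarize_rates(pm_one, 40), "zero lineages")
})

test_that("gain rates follow the published formulas", {
  expect_equal(germline_gain_rate(1, 3, 94 * 40), 1 / 11280,
               tolerance = 1e-15)
  expect_identical(germline_gain_rate(0, 3, 1000), 0)
  expect_identical(germline_gain_rate(2, 1, 100), 0.02)
  expect_error(germline_gain_rate(1, 0, 100), "denominators")

  expect_identical(somatic_gain_rate(5, 25), 0.2)
  expect_identical(somatic_gain_rate(0, 25), 0)
  expect_identical(somatic_gain_rate(25, 25), 1)
  expect_error(somatic_gain_rate(1, 0), "n_ancestral_peaks")
})

test_that("treatment comparison equals the pooled-t closed form", {
  sex <- c(0.2, 0.3, 0.4)
  asex <- c(0.0, 0.1, 0.2)
  cmp <- compare_treatments(sex, asex)
  oracle <- pooled_t_oracle(sex, asex, tails = 1)
  expect_equal(cmp$t_statistic, oracle$t, tolerance = 1e-10)
  expect_equal(cmp$p_value, oracle$p, tolerance = 1e-10)
  expect_identical(cmp$df, 4)

  cmp2 <- compare_treatments(sex, asex, tails = 2)
  expect_equal(cmp2$p_value, pooled_t_oracle(sex, asex, tails = 2)$p,
               tolerance = 1e-10)

  # identical samples: t = 0, one-tailed p = 0.5, no direction
  same <- c(0.1, 0.2, 0.3)
  cmp3 <- compare_treatments(same, same)
  expect_equal(cmp3$t_statistic, 0)
  expect_equal(cmp3$p_value, 0.5)
  expect_identical(cmp3$direction, "none")

  expect_error(compare_treatments(0.1, asex), "at least 2")
})

test_that("somatic-vs-copy-number regression matches normal equations", {
  pts <- data.frame(copy_number = c(2, 7, 7, 27, 130, 346),
                    somatic_rate = c(0.41, 0.30, 0.24, 0.17, 0.05, 0.02))
  fit <- regress_somatic_vs_copy_number(pts)
  oracle <- ols_oracle(pts$copy_number, pts$somatic_rate)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  expect_equal(fit$f_statistic, oracle$f_statistic, tolerance = 1e-10)
  expect_equal(fit$p_value, oracle$p, tolerance = 1e-10)
  expect_lt(fit$slope, 0)

  # collinear points are fit perfectly
  lin <- data.frame(copy_number = 1:4, somatic_rate = 2 - 0.1 * (1:4))
  expect_equal(regress_somatic_vs_copy_number(lin)$r_squared, 1)

  # constant response has nothing to explain
  flat <- data.frame(copy_number = 1:4, somatic_rate = rep(0.3, 4))
  fit0 <- regress_somatic_vs_copy_number(flat)
  expect_identical(fit0$r_squared, 0)
  expect_identical(fit0$p_value, 1)
  expect_equal(fit0$slope, 0, tolerance = 1e-12)

  expect_error(regress_somatic_vs_copy_number(pts[1:2, ]), "at least 3")
})

test_that("ANCOVA decomposition matches a least-squares oracle", {
  toy <- data.frame(
    rate = c(0.40, 0.35, 0.52, 0.48, 0.20, 0.23,
             0.05, 0.02, 0.10, 0.08, 0.01, 0.03),
    treatment = rep(c("sexual", "asexual"), each = 6),
    family = rep(c("F1", "F2", "F3"), times = 4),
    copy_number = rep(c(3, 18, 60), times = 4),
    stringsAsFactors = FALSE)
  out <- ancova_rates(toy)
  expect_identical(out$term, c("treatment", "copy_number"))

  tr <- as.numeric(toy$treatment == "sexual")
  X1 <- cbind(1, tr)
  X2 <- cbind(1, tr, toy$copy_number)
  oracle <- seq_anova_oracle(toy$rate, list(X1, X2))
  expect_equal(out$sum_sq, oracle$sum_sq, tolerance = 1e-10)
  expect_equal(out$f_statistic, oracle$f, tolerance = 1e-10)
  expect_equal(out$p_value, oracle$p, tolerance = 1e-10)

  # all responses equal: nothing to decompose
  toy0 <- toy; toy0$rate <- 0.1
  out0 <- ancova_rates(toy0)
  expect_true(all(out0$f_statistic == 0))
  expect_true(all(out0$p_value == 1))

  # degenerate designs are refused with an explanation
  toy_bad <- toy; toy_bad$copy_number <- 5
  expect_error(ancova_rates(toy_bad), "rank-deficient")
  expect_error(ancova_rates(toy[toy$family == "F1", ]), "2 families")
  expect_error(ancova_rates(toy[toy$treatment == "sexual", ]),
               "both treatments")
})

test_that("observed high-loss counts are compared to the Mendelian bar", {
  n_sex <- 45; n_asex <- 5
  ids <- c(sprintf("S%02d", seq_len(n_sex)), sprintf("A%02d", seq_len(n_asex)))
  treatments <- setNames(rep(c("sexual", "asexual"), c(n_sex, n_asex)), ids)
  m <- matrix(TRUE, length(ids), 2, dimnames = list(ids, c("100", "200")))
  m[1:10, 1] <- FALSE        # 10 sexual losses at locus 100
  m[1:15, 2] <- FALSE        # 15 at locus 200: exceeds 11.25
  pm <- structure(list(presence = m, treatment = treatments),
                  class = "presence_matrix")
  evo <- expected_vs_observed_high_loss(pm, c(100L, 200L))
  expect_equal(evo$expected, c(11.25, 11.25))
  expect_equal(evo$observed, c(10, 15))
  expect_identical(evo$exceeds_expectation, c(FALSE, TRUE))

  # two bouts of selfing raise the expected loss fraction to 0.375
  evo2 <- expected_vs_observed_high_loss(pm, c(100L), n_selfing_bouts = 2)
  expect_equal(evo2$expected, 45 * 0.375)

  # no sexual lineages, no expected losses
  pm_a <- structure(list(presence = m[46:50, , drop = FALSE],
                         treatment = treatments[46:50]),
                    class = "presence_matrix")
  evo0 <- expected_vs_observed_high_loss(pm_a, c(100L))
  expect_true(all(evo0$expected == 0))
})
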