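---
title: "Modelling DNA-transposon dynamics in mutation-accumulation lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA-transposon dynamics in mutation-accumulation lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temaline)
```

## The experiment being modelled

Mutation-accumulation (MA) lines are replicate lineages propagated
through single-individual bottlenecks so that new mutations — here,
gains and losses of DNA-transposon copies — accumulate nearly free of
selection. In a cyclical parthenogen the same clonal genotype can be
propagated either strictly asexually or with occasional induced bouts of
sex; because induced females mate with their sons, one bout of sex is
genetically equivalent to selfing the clonal genotype. At the end of the
experiment each line is assayed by transposon display (TD): a nested-PCR
fingerprint in which every amplified fragment size marks one insertion
locus of the TE family. Each sample is run in triplicate and peaks are
scored as ancestral, new germline (replicable in all three reactions) or
putative somatic (robust but non-replicable).

`temaline` implements this design end to end: closed-form Mendelian
theory (`selfing_offspring_distribution()`, `loss_probability()`,
`state_after_k_selfings()`), a forward simulator
(`run_experiment()`, `emulate_td()`), the TD scoring rubric
(`bin_peaks()` → `identify_ancestral_loci()` → `classify_new_peaks()` →
`build_matrix()`), and rate estimation with treatment statistics
(`summarize_rates()`, `compare_treatments()`, `ancova_rates()`,
`regress_somatic_vs_copy_number()`).

## The single-locus model

A locus carries 0, 1 or 2 copies. Three processes act on it:

* **Segregation (sex only).** Selfing resamples every locus from its
  Mendelian offspring distribution: a heterozygote becomes
  absent / het / hom with probabilities 1/4, 1/2, 1/4; genotypes 0 and 2
  are absorbing. After *k* bouts the heterozygote retains heterozygosity
  (1/2)^k, the remainder split equally between loss and fixation.
  Outcrossing is modelled only against an unoccupied partner (loss
  probability 1/2 for a heterozygote) — the case needed for the
  qualitative ordering clonal ≤ selfing ≤ outcrossing; general partner
  genotypes would need a population model that is out of scope.
* **Local loss (both treatments).** Excision, deletion and mitotic
  recombination are experimentally indistinguishable in a TD assay, so
  they are pooled into a single per-copy per-generation probability
  `excision_rate`. At a homozygous locus an excised copy is restored
  from the intact homologue with `reconstitution_prob` (default 1):
  double-strand-break repair completes within a cell cycle, so
  excisions at one locus are resolved sequentially within a generation
  and a homozygote with perfect repair is never lost.
* **Gain.** Each existing copy seeds a new heterozygous insertion at a
  brand-new locus with `germline_transposition_rate` per generation — a
  fresh insertion occupies one homologue only. Somatic insertions are
  non-heritable by definition, so the simulator draws them once at assay
  time with expected count `somatic_rate × occupied loci`, instead of
  tracking per-generation somatic mosaics it would immediately discard.

Loci are unlinked and segregate independently; linkage, selection,
sex-chromosome genetics and population-level dynamics are deliberately
not modelled.

## Parameters, defaults and rationale

| parameter | default | units | rationale |
|---|---|---|---|
| `n_asexual`, `n_sexual` | 47, 47 | lines | the 94-line, two-treatment MA design |
| `generations_mean` (`_sd`) | 40 (0) | generations | the assay endpoint; per-line variation exists in real data but is secondary, so the default is uniform |
| `n_ancestral_loci` | 25 | loci | a mid-sized TD profile; real families range from a few loci to >100 |
| `fraction_heterozygous` | 0.2 | – | no direct measurement exists; high-loss loci show *some* ancestral sites are heterozygous, and 1 in 5 makes both classes well represented |
| `excision_rate` | 1e-4 | /copy/gen | within the 1e-4–1e-6 span of published DNA-transposon loss rates |
| `reconstitution_prob` | 1 | – | homologue-templated repair is the default fate at homozygous loci |
| `germline_transposition_rate` | 1e-5 | /copy/gen | order of magnitude of single-observation transposition estimates |
| `somatic_rate` | 0.05 | peaks/locus | gives a handful of somatic peaks per lineage, matching the "many new, robust, non-replicable peaks" regime |
| `somatic_replicate_detection` | 0.4 | – | somatic peaks are mosaic and weaker; 0.4 makes 1-of-3 and 2-of-3 patterns common |
| `selfing_generation` | 20 | generation | mid-experiment; real bouts happened at varying generations, configurable |
| `fragment_size_range` | 60–1200 | bp | the sizing window of a 1200-bp calibration ladder |
| `height_meanlog_*`, `height_sdlog` | 7.6 / 6.4 / 0.35 | log units | log-normal peak heights, germline (~2000) above somatic (~600), as in real trace files |
| `height_threshold` | 50 | height units | calibrated so essentially no true peak from the default distributions is discarded (P < 1e-10); real-data thresholds must be user-supplied |

One seed determines a cohort completely: each lineage (and its TD
emulation) runs on a sub-stream derived deterministically from
`(seed, lineage index)`, so cohorts are bit-reproducible and insensitive
to the order in which lineages are inspected.

## Scoring choices

* **Size binning** defaults to exact integer match because the simulator
  emits unique integer fragment sizes; `size_tolerance` merges
  near-identical sizes (single-linkage on sorted sizes, bins labelled by
  their rounded mean) for real fragment-analysis exports.
* **Ancestral call**: a size fully replicable (3/3) in at least
  `min_share = 0.5` of lineages. The share is robust to segregation: a
  heterozygous ancestral locus survives in ~75% of selfed lines and all
  asexual lines, so its share stays ≥ 0.5 even in an all-sexual cohort.
  A side effect is that a recurrent 3/3 size can never be called a
  germline gain (homoplasy falls into the ancestral test first) — with
  ~1100 available sizes and a handful of gains per cohort this is
  vanishingly rare in simulation.
* **Losses** are absences at ancestral sizes in all three replicates of
  a lineage, scored at the single assay endpoint; a locus lost and
  regained in between would be invisible, exactly as in the real assay.
* **High-loss loci** require losses in strictly more than 3 lineages.
* Degenerate inputs: a lineage with ≠3 replicates is an error naming the
  lineage; an all-below-threshold peak table scores as empty, not as an
  error; lineages that lost every band still appear as all-absent rows
  because the matrix roster comes from the treatment map, not from the
  peaks.

## Statistics

* Per-lineage loss rate = row absences / (generations × ancestral
  loci); treatment mean ± SE with SE = sd/√n across lineages, the MA
  convention.
* `compare_treatments()` uses Student's pooled-variance *t*, one-tailed
  (sexual > asexual) by default since the direction is predicted a
  priori by independent assortment; Welch and two-tailed variants by
  flag. When both treatments are internally constant (e.g. no losses at
  all) the test is defined by its limit: t = 0 and p = 0.5 when means
  agree, |t| = ∞ otherwise.
* `ancova_rates()` fits `rate ~ treatment + copy_number` with sequential
  sums of squares (interaction by flag); rank-deficient designs are
  refused with an explanation rather than silently dropped terms.
* `regress_somatic_vs_copy_number()` fits untransformed rate on copy
  number by default, with a log10 option since the scale is not dictated
  by the data. A constant response returns R² = 0, F = 0, p = 1 rather
  than NaN.
* No multiple-testing correction is applied across families by default
  (raw p-values are reported); a Bonferroni adjustment is a one-liner on
  the output if wanted.

All statistics are verified in the test suite against independent
oracles: exact integer gamete enumeration for the selfing chain, the
closed-form pooled *t*, OLS by normal equations, and sequential ANOVA by
explicit least-squares projections, each to 1e-10 on fixed toy tables.

## What the generator does and does not emulate

It reproduces the features the scoring and estimation stages depend on:
a shared ancestor with mixed het/hom loci, treatment-specific selfing
schedules, rare local loss with homologue repair, rare germline gains at
fresh sizes, abundant non-replicable somatic peaks, and triplicate peak
tables that hide allele dosage. It does **not** emulate PCR size bias
against long fragments, peak-height decay with fragment length,
near-coincident sizes from distinct loci, plate-to-plate height drift,
or per-line generation-count variation (supported via `generations_sd`
but off by default). Passing tests therefore demonstrate correctness of
the scoring arithmetic and estimators under clean assay conditions, not
robustness to every artefact of real trace files — for real data the
height threshold and size tolerance must be chosen by inspection.

## Estimator-recovery design

Recovery experiments (in the test suite and `scripts/acceptance.R`) use
an all-heterozygous ancestor. With homozygous loci and perfect
reconstitution the per-copy excision rate is not identifiable from
presence/absence data: hom excisions are repaired, and TD cannot see a
2→1 dosage change. An all-het ancestor makes "losses per ancestral copy
per generation" a direct estimate of the per-copy rate, which the
pipeline recovers within 2 SEs at 5e-4 over 100 cohorts; likewise for a
transposition rate of 1e-4 from scored germline-gain calls.

## Problem sizes used in the checks

The calibration check averages 4000–6000 cohorts of 45 selfed lines at a
single heterozygous locus (loss fraction within 1% of 25%); the
treatment-pattern check runs six full 94-line, 40-generation families
(excision enabled in three); recovery ensembles use 100 cohorts of 47
asexual lines × 25 loci. These sizes keep the whole suite at about a
minute of compute while leaving the stochastic tolerances several
standard errors wide.

## Known limitations

* Two selfing bouts in one lineage reuse the same mid/late-experiment
  spacing rule; real bout timing varied per line and can be emulated
  only by running lineages with custom configs.
* `identify_ancestral_loci()` assumes a single shared ancestor; applying
  it to pooled cohorts from different ancestors would misclassify.
* The ANCOVA treats per-lineage rates as independent observations within
  families, as in the original analysis; a mixed model with a family
  random effect would be the modern alternative.
* Somatic mosaics are summarised by one detection probability per
  replicate; true somatic peak sharing across replicates of one DNA
  extraction is likely more correlated.
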