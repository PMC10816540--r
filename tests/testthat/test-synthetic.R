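test_that("cohort simulation has paired pre/post structure and exact dims", {
  cfg <- scenario_config("cancer_cohorts", seed = 42)
  m <- build_manifest()
  sim <- simulate_cohort(m[1, ], config = cfg)  # endometrium, n = 10
  expect_equal(dim(sim$counts), c(249 + 5 + 6 + 8, 20))
  ann <- sim$counts$annotations
  # every post sample has exactly one pre partner with the same subject
  pre <- ann[ann$timepoint == "pre", ]
  post <- ann[ann$timepoint == "post", ]
  expect_equal(nrow(pre), 10)
  expect_setequal(pre$subject, post$subject)
  expect_false(anyDuplicated(pre$subject) > 0)
  expect_false(anyDuplicated(post$subject) > 0)
  expect_true(all(sim$counts$counts >= 1))
})

test_that("equal config and seed reproduce byte-identical output", {
  cfg <- small_config("lps_flu", seed = 9)
  a <- simulate_lps_flu(cfg)
  b <- simulate_lps_flu(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$effects, b$effects)
  v1 <- simulate_variability(small_config("variability", seed = 5))
  v2 <- simulate_variability(small_config("variability", seed = 5))
  expect_identical(v1$counts, v2$counts)
  q1 <- simulate_qpcr(scenario_config("qpcr", seed = 4))
  q2 <- simulate_qpcr(scenario_config("qpcr", seed = 4))
  expect_identical(q1$cts, q2$cts)
})

test_that("planted cohort effect is recovered by the paired log2 ratio", {
  # Monte-Carlo against the generator's own parameters: with 200 patients the
  # mean paired difference must sit within 3 standard errors of +1.0 log2
  cfg <- small_config("cancer_cohorts", seed = 7)
  row <- build_manifest("table", data.frame(
    protocol_name = "big", n_patients = 200, dose_per_fraction = 2,
    n_fractions = 39))
  panel <- gene_panel(n_targets = 60)
  eff <- planted_effects(panel, up = "BCL6", effect = 1.0)
  sim <- simulate_cohort(row, eff, cfg)
  ann <- sim$counts$annotations
  lg <- log2(sim$counts$counts)
  pre <- ann$sample_id[ann$timepoint == "pre"]
  post <- ann$sample_id[ann$timepoint == "post"]
  d <- lg["BCL6", post] - lg["BCL6", pre]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1.0), 3 * se)
  # null genes drift to zero: grand mean over null genes within 3 SE
  nulls <- setdiff(rownames(lg)[sim$counts$panel$class == "target"], "BCL6")
  dn <- lg[nulls, post] - lg[nulls, pre]
  gm <- mean(rowMeans(dn))
  gse <- sd(rowMeans(dn)) / sqrt(length(nulls))
  expect_lt(abs(gm), 3 * gse + 3 * mean(apply(dn, 1, sd)) / sqrt(ncol(dn)))
})

test_that("effects referencing unknown genes are rejected", {
  cfg <- small_config("cancer_cohorts", seed = 1)
  row <- build_manifest()[1, ]
  panel <- gene_panel(n_targets = 60)
  expect_error(
    simulate_cohort(row, effect_manifest("NOT_A_GENE", 1, "up"), cfg),
    "unknown gene")
  # partial coverage is also invalid
  expect_error(
    simulate_cohort(row, effect_manifest("BCL6", 1, "up"), cfg),
    "every panel target")
})

test_that("LPS/flu arms are donor-paired and the planted effect lands", {
  cfg <- scenario_config("lps_flu", seed = 12)
  sim <- simulate_lps_flu(cfg)
  ann <- sim$counts$annotations
  expect_equal(ncol(sim$counts$counts), 28)
  expect_setequal(unique(ann$condition),
                  c("LPS", "Control_LPS", "Flu", "Control_Flu"))
  expect_equal(unname(table(ann$condition)), rep(7L, 4), ignore_attr = TRUE)

  expr <- normalize_counts(sim$counts)
  s_lps <- compute_slr(expr, "LPS", "Control_LPS")
  planted <- lps_response_genes()
  se <- sd(s_lps$slr[planted]) / sqrt(length(planted))
  expect_lt(abs(mean(s_lps$slr[planted]) - 2.0), 3 * se)

  # flu arm carries no planted effect: mean SLR within 3 SE of zero
  s_flu <- compute_slr(expr, "Flu", "Control_Flu")
  expect_lt(abs(mean(s_flu$slr)), 3 * sd(s_flu$slr) / sqrt(length(s_flu$slr)))
})

test_that("LPS/flu design guards hold", {
  cfg <- small_config("lps_flu", seed = 2)
  expect_error(simulate_lps_flu(cfg, n_donors = 1), "n_donors")
  expect_error(simulate_lps_flu(cfg, planted_up = "NOPE"), "not in panel")
})

test_that("variability design produces persistent donor structure", {
  cfg <- scenario_config("variability", seed = 21)
  cm <- simulate_variability(cfg)
  expect_equal(ncol(cm$counts), 12)
  expect_equal(length(unique(cm$annotations$subject)), 4)
  d <- spearman_distance(row_zscore(normalize_counts(cm)))
  r <- distance_ratio(d, cm$annotations$subject)
  expect_lt(r$within, r$between)
  expect_error(simulate_variability(cfg, n_occasions = 1), "n_occasions")
})

test_that("qPCR simulation matches its calibration truth", {
  cfg <- scenario_config("qpcr", seed = 3, ct_noise_sd = 0)
  sim <- simulate_qpcr(cfg)
  # zero noise and a perfect-doubling truth slope: fitted efficiency 100%
  cv <- fit_standard_curve(sim$dilution[sim$dilution$gene == "BCL6", ])
  expect_equal(cv$efficiency, 100, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)

  # default design: 10 patients x 6 timepoints x 3 replicates per gene
  cfg2 <- scenario_config("qpcr", seed = 3)
  sim2 <- simulate_qpcr(cfg2)
  expect_equal(sum(sim2$cts$gene == "BCL6"), 180)
  expect_error(
    simulate_qpcr(scenario_config("qpcr", seed = 1, qpcr_base_quantity = -1)),
    "positive")

  # calibration quality under the default Ct noise: R^2 > 0.998 in >= 95%
  # of 100 seeds
  r2 <- vapply(1:100, function(i) {
    s <- simulate_qpcr(scenario_config("qpcr", seed = 1000 + i),
                       genes = "BCL6")
    fit_standard_curve(s$dilution[s$dilution$gene == "BCL6", ])$r_squared
  }, numeric(1))
  expect_gte(mean(r2 > 0.998), 0.95)
})
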