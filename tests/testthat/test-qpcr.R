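perfect_curve <- function(slope = -1 / log10(2), intercept = 40,
                          quantities = 10^seq(-4, -9)) {
  data.frame(quantity = quantities, ct = intercept + slope * log10(quantities))
}

test_that("standard curve recovers slope, efficiency and QC status", {
  # exact doubling: slope -3.3219 -> 100% efficiency, R^2 = 1
  cv <- fit_standard_curve(perfect_curve())
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-12)
  expect_equal(cv$efficiency, 100, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_true(cv$qc_pass)

  # slope -3.45 -> ~94.9% efficiency: inside the QC gate
  cv2 <- fit_standard_curve(perfect_curve(slope = -3.45))
  expect_equal(cv2$efficiency, (10^(1 / 3.45) - 1) * 100, tolerance = 1e-9)
  expect_equal(cv2$efficiency, 94.98, tolerance = 0.01)
  expect_true(cv2$qc_pass)

  # slope -3.19 -> ~105.8% efficiency: outside the gate
  cv3 <- fit_standard_curve(perfect_curve(slope = -3.19))
  expect_equal(cv3$efficiency, (10^(1 / 3.19) - 1) * 100, tolerance = 1e-9)
  expect_equal(cv3$efficiency, 105.85, tolerance = 0.01)
  expect_false(cv3$qc_pass)

  expect_error(fit_standard_curve(perfect_curve()[1:2, ]), "3 distinct")
  bad <- perfect_curve()
  bad$quantity[1] <- -1
  expect_error(fit_standard_curve(bad), "positive")
})

test_that("curve conversion round-trips and efficiency is monotone", {
  cv <- fit_standard_curve(perfect_curve(slope = -3.4, intercept = 38))
  q <- 10^runif(50, -10, -3)
  ct <- cv$intercept + cv$slope * log10(q)
  expect_equal(quantity_from_ct(ct, cv), q, tolerance = 1e-9)

  # worked inversion: Ct 20 on slope -3.3219 / intercept 40
  cv2 <- fit_standard_curve(perfect_curve(intercept = 40))
  expect_equal(quantity_from_ct(20, cv2), 1.049e6, tolerance = 1e-3)

  # efficiency strictly decreases as |slope| grows
  effs <- vapply(seq(-3.0, -4.0, by = -0.1), function(s) {
    fit_standard_curve(perfect_curve(slope = s))$efficiency
  }, numeric(1))
  expect_true(all(diff(effs) < 0))
})

test_that("relative expression normalizes to HPRT and pre-exposure", {
  curves <- list(
    G = fit_standard_curve(perfect_curve(intercept = 40)),
    HPRT1 = fit_standard_curve(perfect_curve(intercept = 40)))
  # identical curves and identical Cts: normalized ratio 1, pre fold 1
  cts <- data.frame(
    gene = "G", patient = "p1",
    timepoint = rep(c("pre", "post"), each = 3), replicate = rep(1:3, 2),
    ct = c(25, 25, 25, 24, 24, 24),   # post is one cycle earlier = 2x
    hprt_ct = 25)
  rel <- relative_expression(cts, curves)
  pre <- rel[rel$timepoint == "pre", ]
  post <- rel[rel$timepoint == "post", ]
  expect_equal(pre$normalized, 1, tolerance = 1e-9)
  expect_equal(pre$fold_change, 1, tolerance = 1e-9)
  expect_equal(post$fold_change, 2, tolerance = 1e-9)
  expect_equal(post$log2_fc, 1, tolerance = 1e-9)

  # missing pre-exposure row for a patient is an error
  cts2 <- cts[cts$timepoint != "pre", ]
  expect_error(relative_expression(cts2, curves), "pre-exposure.*p1")
  expect_error(relative_expression(cts, curves["G"]), "HPRT1")

  # QC failure blocks quantification unless overridden
  curves_bad <- list(
    G = fit_standard_curve(perfect_curve(slope = -3.19)),
    HPRT1 = curves$HPRT1)
  expect_error(relative_expression(cts, curves_bad), "failed QC")
  expect_silent(relative_expression(cts, curves_bad, require_qc = FALSE))
})

test_that("Conover post hoc matches the hand-computed rank example", {
  # groups 1-3, 4-6, 7-9: N = 9, k = 3, no ties
  # H = 7.2, S^2 = 7.5, pooled factor = 1, t_AB = -3/sqrt(2/3) = -3.6742
  values <- 1:9
  groups <- rep(c("A", "B", "C"), each = 3)
  out <- conover_test(values, groups)
  expect_equal(nrow(out), 3)
  ab <- out[out$group1 == "A" & out$group2 == "B", ]
  expect_equal(ab$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(ab$p, 2 * pt(-3 / sqrt(2 / 3), 6), tolerance = 1e-12)
  ac <- out[out$group1 == "A" & out$group2 == "C", ]
  expect_equal(ac$statistic, -6 / sqrt(2 / 3), tolerance = 1e-10)
})

test_that("decision tree selects the parametric branch for normal data", {
  set.seed(42)  # seed chosen so Shapiro-Wilk and Bartlett both pass
  vals <- list(a = rnorm(30), b = rnorm(30))
  out <- timepoint_test(vals)
  expect_equal(out$branch, "parametric")
  expect_equal(out$test, "t-test")
  expect_true(all(out$shapiro_p > 0.05))
  expect_gt(out$bartlett_p, 0.05)
})

test_that("decision tree falls back to rank tests for skewed data", {
  set.seed(7)  # exponential samples fail Shapiro-Wilk
  vals <- list(a = rexp(30), b = rexp(30))
  out <- timepoint_test(vals)
  expect_equal(out$branch, "nonparametric")
  expect_equal(out$test, "Mann-Whitney")

  vals3 <- list(a = rexp(20), b = rexp(20), c = rexp(20))
  out3 <- timepoint_test(vals3)
  expect_equal(out3$test, "Kruskal-Wallis")
  expect_true(!is.null(out3$posthoc))
  expect_true(all(out3$posthoc$p >= 0 & out3$posthoc$p <= 1))

  set.seed(42)
  vals3n <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  out3n <- timepoint_test(vals3n)
  expect_equal(out3n$test, "ANOVA")
  expect_equal(nrow(out3n$posthoc), 3)

  # branch override mirrors the plain t-test annotation variant
  outf <- timepoint_test(list(a = rexp(10), b = rexp(10)),
                         force_branch = "parametric")
  expect_equal(outf$test, "t-test")
  expect_error(timepoint_test(list(a = 1:2, b = rnorm(5))), "fewer than 3")
})

test_that("planted post-treatment fold change is detected with power", {
  # 2-fold planted change, 10 patients: the pre vs last_fraction contrast
  # must flag the planted timepoint in well over 70% of runs, consistent
  # with a noncentral-t lower bound
  hits <- vapply(1:100, function(s) {
    sim <- simulate_qpcr(scenario_config("qpcr", seed = 5000 + s),
                         genes = "BCL6")
    curves <- lapply(split(sim$dilution, sim$dilution$gene),
                     fit_standard_curve)
    rel <- relative_expression(sim$cts, curves)
    out <- timepoint_test(list(
      pre = rel$log2_norm[rel$timepoint == "pre"],
      post = rel$log2_norm[rel$timepoint == "last_fraction"]))
    out$significant
  }, logical(1))
  # unpaired noncentral-t power at delta = 1, sd ~ full between-patient
  # spread; the shared-patient design can only beat it
  sd_full <- sqrt(0.5^2 + 0.15^2 + 2 * (0.1^2 / 3))
  ncp <- 1 / (sd_full * sqrt(2 / 10))
  theory <- 1 - pt(qt(0.975, 18), 18, ncp) + pt(-qt(0.975, 18), 18, ncp)
  expect_gte(mean(hits), 0.70)
  expect_gte(mean(hits), theory - 3 * sqrt(theory * (1 - theory) / 100))
})
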