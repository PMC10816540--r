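test_that("paired statistics match the closed-form worked example", {
  # differences 2, 0, 4, 2: mean 2, sd sqrt(8/3)
  out <- paired_stats(c(0, 0, 0, 0), c(2, 0, 4, 2))
  expect_equal(out$d, 1.2247, tolerance = 1e-4)
  expect_equal(out$t, 2.4495, tolerance = 1e-4)
  expect_equal(out$df, 3)
  expect_equal(out$p, 0.0917, tolerance = 1e-3)
})

test_that("degenerate paired inputs are handled explicitly", {
  out <- paired_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out[c("t", "p", "d")], list(t = 0, p = 1, d = 0))
  expect_error(paired_stats(1, 2), "n >= 2")
  expect_error(paired_stats(c(0, 0), c(1, 1)), "zero variance")
})

test_that("paired statistics equal a brute-force oracle to 1e-10", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:20, 1)
    pre <- rnorm(n)
    post <- rnorm(n, sd = runif(1, 0.5, 2))
    got <- paired_stats(pre, post)
    want <- oracle_paired(pre, post)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$d, want$d, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("DE table has calibrated type-I error on null cohorts", {
  # 60 null target genes, 10 pairs, 60 seeds: the p < 0.05 fraction over
  # all gene-seed combinations must sit near the nominal level
  frac <- vapply(1:60, function(s) {
    cfg <- small_config("cancer_cohorts", seed = 7000 + s)
    row <- build_manifest("table", data.frame(
      protocol_name = "null", n_patients = 10, dose_per_fraction = 2,
      n_fractions = 10))
    eff <- planted_effects(gene_panel(n_targets = 60))
    sim <- simulate_cohort(row, eff, cfg)
    tab <- cohort_de_table(normalize_counts(sim$counts), "null")
    mean(tab$p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.05), 0.02)
})

test_that("a planted effect is detected with the expected power", {
  # true paired effect d = 1 at n = 10; empirical power over 200 seeds must
  # clear 75% and agree with the noncentral-t oracle
  set.seed(5)
  hits <- replicate(200, {
    delta <- rnorm(10, mean = 1, sd = 1)
    out <- paired_stats(rep(0, 10), delta)
    out$p < 0.05 && abs(out$d) >= 0.2
  })
  theory <- 1 - stats::pt(stats::qt(0.975, 9), 9, ncp = sqrt(10)) +
    stats::pt(-stats::qt(0.975, 9), 9, ncp = sqrt(10))
  expect_gte(mean(hits), 0.75)
  expect_lt(abs(mean(hits) - theory),
            3 * sqrt(theory * (1 - theory) / 200) + 0.01)
})

test_that("significant planted genes carry the planted direction", {
  cfg <- small_config("cancer_cohorts", seed = 31)
  row <- build_manifest()[1, ]
  panel <- gene_panel(n_targets = 60)
  eff <- planted_effects(panel, up = "BCL6", down = "MYC", effect = 1)
  sim <- simulate_cohort(row, eff, cfg)
  tab <- cohort_de_table(normalize_counts(sim$counts), row$protocol_name)
  expect_s3_class(tab, "de_table")
  expect_equal(nrow(tab), 60)
  expect_equal(tab$df, rep(9, 60))
  b <- tab[tab$gene == "BCL6", ]
  m <- tab[tab$gene == "MYC", ]
  expect_true(!b$significant || b$direction == "up")
  expect_true(!m$significant || m$direction == "down")
  expect_true(all(tab$effect_tier %in% c("negligible", "small", "medium+")))
  expect_error(cohort_de_table(normalize_counts(sim$counts), "nope"),
               "no samples")
  expect_error(
    cohort_de_table(normalize_counts(sim$counts), row$protocol_name,
                    timepoints = c("pre", "week9")), "week9")
})

test_that("signature integration is an intersection with direction", {
  mk_table <- function(sig, dir) {
    structure(data.frame(
      gene = c("g1", "g2", "g3"), protocol = "p",
      mean_diff = ifelse(dir == "up", 1, -1), t = 3, df = 9,
      p = ifelse(sig, 0.01, 0.5), q = 0.1, d = ifelse(dir == "up", 1, -1),
      effect_tier = "medium+", direction = dir, significant = sig,
      stringsAsFactors = FALSE), class = c("de_table", "data.frame"))
  }
  t1 <- mk_table(c(TRUE, TRUE, TRUE), c("up", "up", "down"))
  t2 <- mk_table(c(TRUE, TRUE, FALSE), c("up", "down", "down"))
  out <- integrate_signature(list(t1, t2))
  expect_equal(out$up, "g1")       # up and significant everywhere
  expect_equal(out$down, character(0))  # g2 conflicts, g3 not significant
  expect_error(integrate_signature(list()), "no DE tables")

  # monotone: adding a table can only shrink or preserve the lists
  t3 <- mk_table(c(TRUE, FALSE, FALSE), c("up", "up", "down"))
  out3 <- integrate_signature(list(t1, t2, t3))
  expect_true(all(out3$up %in% out$up))
  expect_true(all(out3$down %in% out$down))
})

test_that("null cohorts integrate to an empty signature", {
  # four protocols, no planted effects: median integrated size 0 over seeds
  m <- build_manifest()
  protos <- setdiff(m$protocol_name, "Prostate_CK")
  sizes <- vapply(1:25, function(s) {
    tabs <- lapply(protos, function(p) {
      cfg <- small_config("cancer_cohorts", seed = s * 37 + match(p, protos))
      eff <- planted_effects(gene_panel(n_targets = 60))
      sim <- simulate_cohort(m[m$protocol_name == p, ], eff, cfg)
      cohort_de_table(normalize_counts(sim$counts), p)
    })
    out <- integrate_signature(tabs)
    length(out$up) + length(out$down)
  }, numeric(1))
  expect_equal(median(sizes), 0)
})
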