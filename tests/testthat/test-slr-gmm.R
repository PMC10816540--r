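# --- signal log ratios ---------------------------------------------------

test_that("SLR is the donor-averaged paired log2 ratio", {
  # single donor, one gene at 400 vs 100 on the linear scale -> SLR = 2
  v <- cbind(t = log2(c(400, 50, 7)), c = log2(c(100, 50, 7)))
  colnames(v) <- c("d1_T", "d1_C")
  expr <- make_expr(v, condition = c("trt", "ctl"), subject = c("d1", "d1"))
  s <- compute_slr(expr, "trt", "ctl")
  expect_equal(unname(s$slr), c(2, 0, 0))
  expect_equal(s$n_pairs, 1)

  # treated exactly equal to control -> all zero
  v2 <- cbind(a = c(5, 6, 7), b = c(5, 6, 7))
  expr2 <- make_expr(v2, condition = c("trt", "ctl"),
                     subject = c("d1", "d1"))
  expect_true(all(compute_slr(expr2, "trt", "ctl")$slr == 0))
})

test_that("cross-condition SLR is the difference of per-condition SLRs", {
  mk <- function(vals) {
    v <- matrix(vals, nrow = 3, ncol = 2)
    rownames(v) <- c("g1", "g2", "g3")
    make_expr(v, condition = c("trt", "ctl"), subject = c("d1", "d1"))
  }
  a <- compute_slr(mk(c(2, 2, 2, 0, 0, 0)), "trt", "ctl")   # SLR 2.0
  b <- compute_slr(mk(c(0.5, 0.5, 0.5, 0, 0, 0)), "trt", "ctl")  # SLR 0.5
  cc <- cross_condition_slr(a, b)
  expect_equal(unname(cc$slr), rep(1.5, 3))
})

test_that("unpaired samples are rejected", {
  v <- matrix(rnorm(12), 3, 4)
  colnames(v) <- c("a", "b", "c", "d")
  expr <- make_expr(v, condition = c("trt", "trt", "ctl", "ctl"),
                    subject = c("d1", "d2", "d1", "d3"))
  expect_error(compute_slr(expr, "trt", "ctl"), "paired")
})

# --- mixture model fitting ------------------------------------------------

test_that("BIC selects a single component for pure noise", {
  ks <- vapply(1:20, function(i) {
    set.seed(i)
    slr_gmm(rnorm(1000), seed = i)$K
  }, integer(1))
  expect_gte(sum(ks == 1), 19)
})

test_that("a clear two-component mixture is recovered", {
  set.seed(7)
  x <- c(rnorm(250, 0, 0.2), rnorm(250, 3, 0.3))
  fit <- slr_gmm(x, seed = 7)
  expect_equal(fit$K, 2L)
  mu <- sort(fit$means)
  expect_lt(abs(mu[1] - 0), 0.1)
  expect_lt(abs(mu[2] - 3), 0.1)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$sds > 0))
  expect_equal(fit$null_component, which.min(abs(fit$means)))
})

test_that("an all-identical input engages the sigma floor", {
  fit <- slr_gmm(rep(1.5, 50), seed = 1)
  expect_equal(fit$K, 1L)
  expect_true(fit$degenerate)
  expect_true(fit$sds > 0)
})

test_that("EM log-likelihood is monotone and BIC recomputes exactly", {
  set.seed(11)
  x <- c(rnorm(150, 0, 0.3), rnorm(60, 2, 0.4))
  fit <- slr_gmm(x, seed = 11)
  # monotone within the final run, checked at every iteration
  expect_true(all(diff(fit$logL_trace) >= -1e-8))
  # BIC = (3K - 1) ln n - 2 logL, recomputed externally for all candidates
  expect_equal(fit$candidates$bic,
               (3 * fit$candidates$K - 1) * log(fit$n) -
                 2 * fit$candidates$logL)
  expect_equal(fit$bic, (3 * fit$K - 1) * log(fit$n) - 2 * fit$logL)
  # logLik method agrees
  expect_equal(as.numeric(logLik(fit)), fit$logL)
  expect_equal(attr(logLik(fit), "df"), 3 * fit$K - 1)
  expect_error(slr_gmm(1.2), "n >= 2")
})

test_that("fitted parameters agree with an independent mixture fitter", {
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(21)
  x <- c(rnorm(300, 0, 0.25), rnorm(100, 2.5, 0.35))
  fit <- slr_gmm(x, seed = 21)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$K, 2L)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(fit$logL, mc$loglik, tolerance = 0.01)
})

# --- classification -------------------------------------------------------

test_that("a single-component fit calls every gene similar", {
  set.seed(2)
  fit <- slr_gmm(rnorm(200, 0, 0.2), seed = 2)
  expect_equal(fit$K, 1L)
  cl <- classify_genes(fit)
  expect_true(all(cl$call == "similar"))
  expect_length(attr(cl, "thresholds"), 0)
})

test_that("calls are consistent with the reported thresholds", {
  set.seed(5)
  x <- c(rnorm(200, 0, 0.15), rnorm(30, 2, 0.3), rnorm(20, -1.5, 0.2))
  fit <- slr_gmm(x, seed = 5)
  cl <- classify_genes(fit)
  thr <- attr(cl, "thresholds")
  seg <- attr(cl, "segment_calls")
  expect_equal(length(seg), length(thr) + 1)
  by_threshold <- seg[findInterval(cl$slr, thr) + 1]
  expect_equal(unname(by_threshold), cl$call)
  # a gene exactly at the null mean is similar
  at_null <- predict(fit, fit$means[fit$null_component])
  expect_equal(unname(at_null), "similar")
  # posteriors sum to one
  post <- predict(fit, type = "posterior")
  expect_equal(unname(rowSums(post)), rep(1, length(x)), tolerance = 1e-9)
})

test_that("planted up-regulated set is recovered at the published size", {
  # 222 null + 27 planted genes mirroring the LPS response experiment
  ups <- vapply(1:20, function(s) {
    set.seed(s)
    x <- c(rnorm(222, 0, 0.15), rnorm(27, 2, 0.3))
    fit <- slr_gmm(x, seed = s)
    sum(classify_genes(fit)$call == "up")
  }, numeric(1))
  expect_equal(median(ups), 27)
})

test_that("no up or down calls arise without planted effects", {
  counts <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(249, 0, 0.12)
    cl <- classify_genes(slr_gmm(x, seed = s))
    sum(cl$call != "similar")
  }, numeric(1))
  expect_equal(median(counts), 0)
})

test_that("model methods behave like a classed fit object", {
  set.seed(3)
  x <- c(rnorm(100, 0, 0.2), rnorm(40, 1.5, 0.2))
  names(x) <- sprintf("g%03d", seq_along(x))
  fit <- slr_gmm(x, seed = 3)
  expect_output(print(fit), "selected by BIC")
  expect_output(summary(fit), "Candidate models")
  co <- coef(fit)
  expect_equal(colnames(co), c("weight", "mean", "sd"))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2 * fit$n)
  expect_length(residuals(fit), fit$n)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
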