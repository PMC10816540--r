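#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct against log10(quantity) over a serial-dilution
#' series. The amplification efficiency is `10^(-1/slope) - 1` (as a
#' percentage; a slope of -3.3219 Ct per decade is perfect doubling, 100%).
#' The curve passes QC when the efficiency lies in [93%, 103%] and
#' R^2 > 0.998.
#'
#' @param dilution data.frame with columns `quantity` (> 0) and `ct`;
#'   at least 3 distinct dilution points.
#' @param gene optional gene label stored on the curve.
#' @return object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency` (percent), `qc_pass`, `gene`, `n`.
#' @examples
#' q <- 10^seq(-4, -9, by = -1)
#' fit_standard_curve(data.frame(quantity = q, ct = 40 - 1/log10(2) * log10(q)))
#' @export
fit_standard_curve <- function(dilution, gene = NA_character_) {
  stopifnot(is.data.frame(dilution),
            all(c("quantity", "ct") %in% names(dilution)))
  if (any(dilution$quantity <= 0)) {
    stop_radsig("dilution quantities must be positive")
  }
  if (length(unique(dilution$quantity)) < 3) {
    stop_radsig("standard curve needs >= 3 distinct dilution points")
  }
  fit <- stats::lm(ct ~ log10(quantity), data = dilution)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # R^2 computed directly (summary.lm warns on noise-free calibration data)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((dilution$ct - mean(dilution$ct))^2)
  eff <- (10^(-1 / slope) - 1) * 100
  structure(list(gene = gene, slope = slope, intercept = intercept,
                 r_squared = r2, efficiency = eff,
                 qc_pass = eff >= 93 && eff <= 103 && r2 > 0.998,
                 n = nrow(dilution)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve%s: slope %.4f, intercept %.3f, R^2 %.5f, eff %.1f%% [%s]\n",
    if (is.na(x$gene)) "" else paste0(" (", x$gene, ")"),
    x$slope, x$intercept, x$r_squared, x$efficiency,
    if (x$qc_pass) "QC pass" else "QC FAIL"))
  invisible(x)
}

#' Invert a standard curve: Ct to transcript quantity
#' @param ct numeric Ct values
#' @param curve a [fit_standard_curve()] result
#' @return quantities `10^((ct - intercept) / slope)`
#' @export
quantity_from_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Standard-curve relative quantification
#'
#' Converts triplicate Ct values to transcript quantities through each
#' gene's standard curve (replicates are averaged on the Ct scale first),
#' normalizes to the HPRT1 internal control, and expresses each patient x
#' timepoint value as a fold change over that patient's own pre-exposure
#' value. Log2-transformed columns are added for downstream statistics.
#'
#' @param cts long-format Ct table: columns `gene`, `patient`, `timepoint`,
#'   `replicate`, `ct`, `hprt_ct` (as from [simulate_qpcr()]).
#' @param curves named list of [fit_standard_curve()] results, one per
#'   target gene plus `HPRT1`.
#' @param require_qc refuse curves that fail QC (default `TRUE`).
#' @param baseline `"patient"` (each patient's own pre value; default) or
#'   `"cohort"` (mean pre value across patients).
#' @return data.frame with one row per gene x patient x timepoint:
#'   `quantity`, `hprt_quantity`, `normalized`, `fold_change`, `log2_norm`,
#'   `log2_fc`.
#' @export
relative_expression <- function(cts, curves, require_qc = TRUE,
                                baseline = c("patient", "cohort")) {
  baseline <- match.arg(baseline)
  stopifnot(all(c("gene", "patient", "timepoint", "ct", "hprt_ct") %in%
                  names(cts)))
  if (!"HPRT1" %in% names(curves)) {
    stop_radsig("a standard curve for the HPRT1 control is required")
  }
  genes <- unique(cts$gene)
  miss <- setdiff(genes, names(curves))
  if (length(miss)) {
    stop_radsig("missing standard curve(s) for: ", paste(miss, collapse = ", "))
  }
  if (require_qc) {
    bad <- names(curves)[!vapply(curves, `[[`, logical(1), "qc_pass")]
    if (length(bad)) {
      stop_radsig("standard curve(s) failed QC (93-103% efficiency, ",
                  "R^2 > 0.998): ", paste(bad, collapse = ", "),
                  "; use require_qc = FALSE to override")
    }
  }
  # mean Ct over replicates per gene x patient x timepoint
  key <- interaction(cts$gene, cts$patient, cts$timepoint, drop = TRUE)
  agg <- data.frame(
    gene = tapply(cts$gene, key, `[`, 1),
    patient = tapply(cts$patient, key, `[`, 1),
    timepoint = tapply(cts$timepoint, key, `[`, 1),
    ct = as.numeric(tapply(cts$ct, key, mean)),
    hprt_ct = as.numeric(tapply(cts$hprt_ct, key, mean)),
    stringsAsFactors = FALSE
  )
  rownames(agg) <- NULL
  hprt <- curves[["HPRT1"]]
  agg$quantity <- vapply(seq_len(nrow(agg)), function(i) {
    quantity_from_ct(agg$ct[i], curves[[agg$gene[i]]])
  }, numeric(1))
  agg$hprt_quantity <- quantity_from_ct(agg$hprt_ct, hprt)
  agg$normalized <- agg$quantity / agg$hprt_quantity

  pre <- agg[agg$timepoint == "pre", ]
  if (baseline == "patient") {
    key_gp <- paste(agg$gene, agg$patient)
    pre_val <- stats::setNames(pre$normalized, paste(pre$gene, pre$patient))
    miss <- unique(agg$patient[!(key_gp %in% names(pre_val))])
    if (length(miss)) {
      stop_radsig("missing pre-exposure value for patient(s): ",
                  paste(miss, collapse = ", "))
    }
    agg$fold_change <- agg$normalized / pre_val[key_gp]
  } else {
    if (nrow(pre) == 0) stop_radsig("no pre-exposure samples found")
    base <- tapply(pre$normalized, pre$gene, mean)
    agg$fold_change <- agg$normalized / base[agg$gene]
  }
  agg$log2_norm <- log2(agg$normalized)
  agg$log2_fc <- log2(agg$fold_change)
  agg
}

#' Conover-Iman all-pairs rank comparison
#'
#' Post hoc test after a Kruskal-Wallis ANOVA: pairwise t statistics on rank
#' means with the tie-corrected pooled rank variance,
#' `t_ij = (Rbar_i - Rbar_j) / sqrt(S^2 (N-1-H)/(N-k) (1/n_i + 1/n_j))`,
#' referred to a t distribution with `N - k` degrees of freedom.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups).
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `statistic`, `p`.
#' @export
conover_test <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop_radsig("Conover test needs >= 2 groups")
  N <- length(values)
  r <- rank(values)
  H <- unname(stats::kruskal.test(values, groups)$statistic)
  rbar <- tapply(r, groups, mean)
  ni <- tabulate(groups)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  mult <- S2 * (N - 1 - H) / (N - k)
  pairs <- utils::combn(levels(groups), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    stringsAsFactors = FALSE)
  i1 <- match(out$group1, levels(groups))
  i2 <- match(out$group2, levels(groups))
  out$statistic <- (rbar[i1] - rbar[i2]) /
    sqrt(mult * (1 / ni[i1] + 1 / ni[i2]))
  out$p <- 2 * stats::pt(-abs(out$statistic), N - k)
  rownames(out) <- NULL
  out
}

#' Per-timepoint decision-tree test
#'
#' Implements the parametric/nonparametric branching used for relative
#' qPCR expression at each timepoint: the branch is parametric iff every
#' group passes the Shapiro-Wilk normality test (alpha 0.05) *and*
#' Bartlett's variance-homogeneity test has p > 0.05. Then
#'
#' * 2 groups: Student t-test (parametric) or Mann-Whitney (nonparametric);
#' * more than 2: one-way ANOVA with Tukey HSD post hoc (parametric) or
#'   Kruskal-Wallis with Conover post hoc (nonparametric).
#'
#' No multiple-testing correction is applied; results with p < 0.05 are
#' flagged significant.
#'
#' @param values named list of numeric vectors, one per group; every group
#'   needs >= 3 values (for the normality check).
#' @param gene,timepoint optional labels carried into the result.
#' @param alpha significance level for the assumption gates and the flag.
#' @param force_branch `NULL` (decide from the data; default),
#'   `"parametric"` or `"nonparametric"` to bypass the decision tree (the
#'   plain t-test variant used in figure annotations).
#' @return object of class `timepoint_stats`: list with `branch`, `test`,
#'   `statistic`, `p`, `significant`, `shapiro_p` (per group),
#'   `bartlett_p`, `posthoc` (data.frame or NULL), `gene`, `timepoint`.
#' @export
timepoint_test <- function(values, gene = NA_character_,
                           timepoint = NA_character_, alpha = 0.05,
                           force_branch = NULL) {
  stopifnot(is.list(values), length(values) >= 2)
  if (is.null(names(values))) {
    names(values) <- paste0("group", seq_along(values))
  }
  small <- names(values)[vapply(values, length, integer(1)) < 3]
  if (length(small)) {
    stop_radsig("group(s) with fewer than 3 values: ",
                paste(small, collapse = ", "))
  }
  shapiro_p <- vapply(values, function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: clearly non-normal branch
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), vapply(values, length, integer(1))))
  bartlett_p <- tryCatch(stats::bartlett.test(x, g)$p.value,
                         error = function(e) 0)
  parametric <- all(shapiro_p > alpha) && bartlett_p > alpha
  if (!is.null(force_branch)) {
    parametric <- match.arg(force_branch,
                            c("parametric", "nonparametric")) == "parametric"
  }
  posthoc <- NULL
  if (length(values) == 2) {
    if (parametric) {
      ht <- stats::t.test(values[[1]], values[[2]], var.equal = TRUE)
      test <- "t-test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(values[[1]], values[[2]]))
      test <- "Mann-Whitney"
    }
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    if (parametric) {
      fit <- stats::aov(x ~ g)
      an <- summary(fit)[[1]]
      statistic <- an[["F value"]][1]
      p <- an[["Pr(>F)"]][1]
      test <- "ANOVA"
      tk <- stats::TukeyHSD(fit)$g
      posthoc <- data.frame(
        comparison = rownames(tk), diff = tk[, "diff"],
        p = tk[, "p adj"], row.names = NULL, stringsAsFactors = FALSE)
    } else {
      ht <- stats::kruskal.test(x, g)
      statistic <- unname(ht$statistic)
      p <- ht$p.value
      test <- "Kruskal-Wallis"
      co <- conover_test(x, g)
      posthoc <- data.frame(
        comparison = paste(co$group1, co$group2, sep = "-"),
        statistic = co$statistic, p = co$p, stringsAsFactors = FALSE)
    }
  }
  structure(list(gene = gene, timepoint = timepoint,
                 branch = if (parametric) "parametric" else "nonparametric",
                 test = test, statistic = statistic, p = p,
                 significant = p < alpha,
                 shapiro_p = shapiro_p, bartlett_p = bartlett_p,
                 posthoc = posthoc),
            class = "timepoint_stats")
}

#' @export
print.timepoint_stats <- function(x, ...) {
  cat(sprintf("timepoint_stats%s%s: %s branch, %s, stat %.4f, p %.4g%s\n",
              if (is.na(x$gene)) "" else paste0(" ", x$gene),
              if (is.na(x$timepoint)) "" else paste0(" @", x$timepoint),
              x$branch, x$test, x$statistic, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}
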