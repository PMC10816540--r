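#' Paired t statistic with Cohen's d
#'
#' For paired differences `delta_i = post_i - pre_i`:
#' `t = mean(delta) / (sd(delta) / sqrt(n))` with `n - 1` degrees of
#' freedom, two-sided p from the t distribution, and the paired Cohen's d
#' (`dz`) `d = mean(delta) / sd(delta)`.
#'
#' @param pre,post numeric vectors aligned by subject (same order), n >= 2.
#' @return list with `t`, `df`, `p`, `d`, `mean_diff`, `n`.
#' @examples
#' paired_stats(c(0, 0, 0, 0), c(2, 0, 4, 2))  # d = 1.2247, t = 2.4495
#' @export
paired_stats <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop_radsig("pre and post must be aligned vectors of equal length")
  }
  n <- length(pre)
  if (n < 2) stop_radsig("paired statistics need n >= 2 pairs")
  delta <- post - pre
  m <- mean(delta)
  s <- stats::sd(delta)
  if (s == 0) {
    if (m != 0) {
      stop_radsig("degenerate pairs: zero variance with non-zero mean ",
                  "difference")
    }
    return(list(t = 0, df = n - 1, p = 1, d = 0, mean_diff = 0, n = n))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), d = m / s,
       mean_diff = m, n = n)
}

cohen_tier <- function(d) {
  ad <- abs(d)
  ifelse(ad < 0.2, "negligible", ifelse(ad < 0.5, "small", "medium+"))
}

#' Per-protocol paired differential expression table
#'
#' Runs a paired t-test per target gene between two timepoints of one
#' treatment protocol, qualified by the paired Cohen's d. A gene is flagged
#' significant when `p < 0.05` and `|d| >= d_threshold`; the default
#' `d_threshold = 0.2` admits effects of at least small size (set `0.5` for
#' medium and above). No multiple-testing correction is applied to the
#' significance flag; Benjamini-Hochberg adjusted values are reported as the
#' annotation column `q` only.
#'
#' @param expr an [expr_matrix()]; annotations need `subject`, `timepoint`
#'   and (unless `protocol = NULL`) `protocol` columns.
#' @param protocol protocol label to subset on, or `NULL` to use all samples.
#' @param timepoints length-2 character vector `c(pre, post)`.
#' @param d_threshold minimum `|d|` for the significance flag.
#' @param alpha p-value cutoff (default 0.05).
#' @return data.frame of class `de_table`: one row per target gene with
#'   `gene`, `protocol`, `mean_diff`, `t`, `df`, `p`, `q`, `d`,
#'   `effect_tier`, `direction`, `significant`.
#' @export
cohort_de_table <- function(expr, protocol = NULL,
                            timepoints = c("pre", "post"),
                            d_threshold = 0.2, alpha = 0.05) {
  stopifnot(inherits(expr, "expr_matrix"), length(timepoints) == 2)
  ann <- expr$annotations
  if (!is.null(protocol)) {
    ann <- ann[ann$protocol == protocol, , drop = FALSE]
    if (nrow(ann) == 0) stop_radsig("no samples for protocol '", protocol, "'")
  }
  miss <- setdiff(timepoints, ann$timepoint)
  if (length(miss)) {
    stop_radsig("timepoint(s) missing from data: ",
                paste(miss, collapse = ", "))
  }
  pre <- ann[ann$timepoint == timepoints[1], ]
  post <- ann[ann$timepoint == timepoints[2], ]
  common <- intersect(pre$subject, post$subject)
  if (length(common) < 2) {
    stop_radsig("need >= 2 complete pre/post pairs, found ", length(common))
  }
  pre <- pre[match(common, pre$subject), ]
  post <- post[match(common, post$subject), ]
  targets <- panel_genes(expr$panel, "target")
  delta <- expr$values[targets, post$sample_id, drop = FALSE] -
    expr$values[targets, pre$sample_id, drop = FALSE]
  n <- length(common)
  m <- rowMeans(delta)
  s <- row_sds(delta)
  if (any(s == 0 & m != 0)) {
    stop_radsig("degenerate gene(s) with zero difference variance: ",
                paste(targets[s == 0 & m != 0], collapse = ", "))
  }
  t <- ifelse(s == 0, 0, m / (s / sqrt(n)))
  p <- ifelse(s == 0, 1, 2 * stats::pt(-abs(t), n - 1))
  d <- ifelse(s == 0, 0, m / s)
  out <- data.frame(
    gene = targets,
    protocol = protocol %||% "all",
    mean_diff = m,
    t = t,
    df = n - 1,
    p = p,
    q = stats::p.adjust(p, "BH"),
    d = d,
    effect_tier = cohen_tier(d),
    direction = ifelse(m >= 0, "up", "down"),
    significant = p < alpha & abs(d) >= d_threshold,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("de_table", "data.frame"),
            n_pairs = n, timepoints = timepoints)
}

#' Integrate significant genes across treatment protocols
#'
#' A gene enters the integrated up (down) list iff it is flagged significant
#' with direction up (down) in *every* supplied protocol table - the
#' intersection-with-concordant-direction rule behind a cross-cancer common
#' signature. Adding a protocol can therefore only shrink or preserve the
#' lists.
#'
#' @param tables list of [cohort_de_table()] results (>= 1; typically one
#'   per protocol, with differently fractionated protocols such as SBRT
#'   excluded upstream).
#' @return object of class `integrated_signature`: list with `up`, `down`
#'   (character vectors), and `evidence` (per gene and protocol: p, d,
#'   direction, significant).
#' @export
integrate_signature <- function(tables) {
  if (length(tables) == 0) stop_radsig("no DE tables supplied")
  if (!all(vapply(tables, inherits, logical(1), "de_table"))) {
    stop_radsig("all elements must be cohort_de_table() results")
  }
  genes <- tables[[1]]$gene
  for (t in tables) {
    if (!identical(t$gene, genes)) {
      stop_radsig("DE tables cover different gene sets")
    }
  }
  sig_up <- Reduce(`&`, lapply(tables, function(t) {
    t$significant & t$direction == "up"
  }))
  sig_down <- Reduce(`&`, lapply(tables, function(t) {
    t$significant & t$direction == "down"
  }))
  evidence <- do.call(rbind, lapply(tables, function(t) {
    t[, c("gene", "protocol", "p", "d", "direction", "significant")]
  }))
  rownames(evidence) <- NULL
  structure(list(up = genes[sig_up], down = genes[sig_down],
                 evidence = evidence,
                 protocols = vapply(tables, function(t) t$protocol[1],
                                    character(1))),
            class = "integrated_signature")
}

#' @export
print.integrated_signature <- function(x, ...) {
  cat("integrated_signature across",
      length(x$protocols), "protocol(s):",
      paste(x$protocols, collapse = ", "), "\n")
  cat("  up  (", length(x$up), "): ",
      paste(x$up, collapse = ", "), "\n", sep = "")
  cat("  down(", length(x$down), "): ",
      paste(x$down, collapse = ", "), "\n", sep = "")
  invisible(x)
}
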