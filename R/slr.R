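#' Per-gene signal log ratios for a paired contrast
#'
#' The signal log ratio (SLR) of a gene is the log2 ratio of treated to
#' control expression. With donor-paired samples it is computed per donor as
#' the paired log2 difference (the matrices are already on the log2 scale)
#' and averaged across donors.
#'
#' @param expr an [expr_matrix()]; annotations must carry `condition` and
#'   `subject` columns.
#' @param treated_arm,control_arm condition labels of the two arms; each
#'   treated sample must pair with exactly one control sample of the same
#'   subject.
#' @param contrast label stored on the result (defaults to
#'   `"treated/control"`).
#' @return an object of class `slr_set`: list with `slr` (named numeric, one
#'   value per target gene), `contrast`, `n_pairs`.
#' @examples
#' cfg <- scenario_config("lps_flu", seed = 1, n_targets = 60)
#' sim <- simulate_lps_flu(cfg, planted_up = c("IL6", "TNF"))
#' s <- compute_slr(normalize_counts(sim$counts), "LPS", "Control_LPS")
#' round(s$slr[c("IL6", "TNF")], 2)
#' @export
compute_slr <- function(expr, treated_arm, control_arm, contrast = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  ann <- expr$annotations
  if (is.null(ann$condition) || is.null(ann$subject)) {
    stop_radsig("annotations need 'condition' and 'subject' columns")
  }
  tr <- ann[ann$condition == treated_arm, ]
  ct <- ann[ann$condition == control_arm, ]
  if (nrow(tr) == 0 || nrow(ct) == 0) {
    stop_radsig("arm not found: ",
                paste(setdiff(c(treated_arm, control_arm), ann$condition),
                      collapse = ", "))
  }
  if (anyDuplicated(tr$subject) || anyDuplicated(ct$subject) ||
      !setequal(tr$subject, ct$subject)) {
    stop_radsig("samples are not 1:1 paired by subject between arms '",
                treated_arm, "' and '", control_arm, "'")
  }
  ct <- ct[match(tr$subject, ct$subject), ]
  targets <- panel_genes(expr$panel, "target")
  diffs <- expr$values[targets, tr$sample_id, drop = FALSE] -
    expr$values[targets, ct$sample_id, drop = FALSE]
  structure(list(slr = rowMeans(diffs),
                 contrast = contrast %||% paste0(treated_arm, "/", control_arm),
                 n_pairs = nrow(tr)),
            class = "slr_set")
}

#' Cross-condition signal log ratio
#'
#' The log2 ratio of two conditions' treated/control ratios, i.e. the
#' difference of their SLRs: genes responding identically in both conditions
#' land near zero regardless of the size of the common response.
#'
#' @param slr_a,slr_b two [compute_slr()] results over the same genes.
#' @return an `slr_set` with contrast `"<a> vs <b>"`.
#' @export
cross_condition_slr <- function(slr_a, slr_b) {
  stopifnot(inherits(slr_a, "slr_set"), inherits(slr_b, "slr_set"))
  if (!identical(names(slr_a$slr), names(slr_b$slr))) {
    stop_radsig("SLR sets cover different genes")
  }
  structure(list(slr = slr_a$slr - slr_b$slr,
                 contrast = paste0(slr_a$contrast, " vs ", slr_b$contrast),
                 n_pairs = min(slr_a$n_pairs, slr_b$n_pairs)),
            class = "slr_set")
}

#' @export
print.slr_set <- function(x, ...) {
  cat("slr_set [", x$contrast, "]: ", length(x$slr), " genes, ",
      x$n_pairs, " pairs\n", sep = "")
  print(summary(unname(x$slr)))
  invisible(x)
}
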