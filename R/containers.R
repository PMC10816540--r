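#' Count matrix container
#'
#' Binds a non-negative integer gene-by-sample count matrix to a
#' [gene_panel()] and a per-sample annotation table. Columns of `counts`
#' must match `annotations$sample_id` one-to-one and in order.
#'
#' @param counts integer matrix, genes x samples, with rownames = probe ids
#'   and colnames = sample ids.
#' @param panel a [gene_panel()] covering exactly the rownames of `counts`.
#' @param annotations data.frame with at least a `sample_id` column;
#'   typically also `subject`, `group`, `condition`, `timepoint`, `protocol`,
#'   `batch`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, panel, annotations) {
  stopifnot(is.matrix(counts), inherits(panel, "gene_panel"),
            is.data.frame(annotations))
  if (is.null(annotations$sample_id)) {
    stop_radsig("annotations must have a 'sample_id' column")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop_radsig("negative count for gene '", rownames(counts)[bad[1]],
                "' in sample '", colnames(counts)[bad[2]], "'")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_radsig("duplicate gene ids in count matrix: ",
                paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                      collapse = ", "))
  }
  if (!setequal(rownames(counts), panel$gene)) {
    stop_radsig("count matrix rows do not match the panel probe ids")
  }
  unmatched <- setdiff(colnames(counts), annotations$sample_id)
  if (length(unmatched)) {
    stop_radsig("sample(s) missing from annotations: ",
                paste(unmatched, collapse = ", "))
  }
  extra <- setdiff(annotations$sample_id, colnames(counts))
  if (length(extra)) {
    stop_radsig("annotation sample(s) absent from counts: ",
                paste(extra, collapse = ", "))
  }
  annotations <- annotations[match(colnames(counts), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  panel <- panel[match(rownames(counts), panel$gene), , drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, panel = panel, annotations = annotations),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "probes x", ncol(x$counts),
      "samples\n")
  cat("  probe classes:",
      paste(names(table(x$panel$class)), table(x$panel$class),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Log2 expression matrix container
#'
#' Real-valued genes x samples matrix on the log2 scale together with the
#' panel, annotations, and a provenance record listing every processing step
#' applied, in order.
#'
#' @param values numeric matrix (log2 scale), genes x samples.
#' @param panel,annotations as in [count_matrix()].
#' @param provenance character vector of applied steps.
#' @param constant_rows character vector of gene ids flagged as constant by
#'   [row_zscore()] (zeroed rows).
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, panel, annotations, provenance = character(),
                        constant_rows = character()) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(is.finite(values))) stop_radsig("expression values must be finite")
  structure(list(values = values, panel = panel, annotations = annotations,
                 provenance = provenance, constant_rows = constant_rows),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples (log2)\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Planted-effect manifest
#'
#' Ground-truth record for simulated data: one row per target gene (and per
#' contrast, where a scenario has several) giving the planted log2 fold
#' change and its class. Null genes carry a log2 fold change of exactly zero;
#' the sign of a non-zero effect must match its class.
#'
#' @param gene character vector of target gene ids.
#' @param true_log2fc numeric planted log2 fold changes.
#' @param class `"up"`, `"down"` or `"null"` per gene.
#' @param contrast optional contrast/condition label per row.
#' @return data.frame of class `effect_manifest`.
#' @export
effect_manifest <- function(gene, true_log2fc, class, contrast = NULL) {
  stopifnot(length(gene) == length(true_log2fc),
            length(gene) == length(class))
  class <- match.arg(class, c("up", "down", "null"), several.ok = TRUE)
  bad_null <- class == "null" & true_log2fc != 0
  bad_sign <- (class == "up" & true_log2fc <= 0) |
    (class == "down" & true_log2fc >= 0)
  if (any(bad_null) || any(bad_sign)) {
    stop_radsig("effect classes inconsistent with log2 fold changes for: ",
                paste(gene[bad_null | bad_sign], collapse = ", "))
  }
  out <- data.frame(gene = gene, true_log2fc = true_log2fc, class = class,
                    stringsAsFactors = FALSE)
  if (!is.null(contrast)) out$contrast <- contrast
  structure(out, class = c("effect_manifest", "data.frame"))
}

# build an effect manifest covering all panel targets from planted lists
planted_effects <- function(panel, up = character(), down = character(),
                            effect = 1, contrast = NULL) {
  targets <- panel_genes(panel, "target")
  unknown <- setdiff(c(up, down), targets)
  if (length(unknown)) {
    stop_radsig("planted effect genes not in panel: ",
                paste(unknown, collapse = ", "))
  }
  lfc <- numeric(length(targets))
  names(lfc) <- targets
  lfc[up] <- abs(effect)
  lfc[down] <- -abs(effect)
  cls <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "null"))
  effect_manifest(targets, unname(lfc), unname(cls),
                  contrast = if (is.null(contrast)) NULL
                             else rep(contrast, length(targets)))
}
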