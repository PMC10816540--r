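#' Write / read count matrices as TSV
#'
#' The on-disk layout is one counts TSV (first column `gene`, one column per
#' sample id) plus one annotation TSV keyed by `sample_id`. Probe classes are
#' taken from an optional panel file (TSV with columns `gene`, `class`) or
#' inferred from the `HK_`/`POS_`/`NEG_` name prefixes.
#'
#' @param x a [count_matrix()]
#' @param path counts TSV path
#' @param annotation_path annotation TSV path
#' @param panel_path optional panel TSV path; written alongside by
#'   `write_count_matrix()`.
#' @return `write_count_matrix()` returns `x` invisibly; `read_count_table()`
#'   returns a validated [count_matrix()].
#' @export
write_count_matrix <- function(x, path, annotation_path,
                               panel_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$annotations, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(panel_path)) {
    utils::write.table(x$panel, panel_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' @rdname write_count_matrix
#' @export
read_count_table <- function(path, annotation_path, panel_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_radsig("count table needs a gene column plus samples")
  genes <- as.character(df[[1]])
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop_radsig("non-numeric counts in ", path)
  rownames(counts) <- genes
  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  panel <- if (!is.null(panel_path)) {
    p <- utils::read.table(panel_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    gene_panel(p$gene, p$class)
  } else {
    infer_panel(genes)
  }
  count_matrix(counts, panel, ann)
}

#' Read RCC-lite per-sample count files
#'
#' A minimal plain-text per-sample format: lines of `gene,class,count`
#' (header `gene,class,count` optional). One file per sample; the sample id
#' is the file name without extension unless given in `sample_ids`.
#'
#' @param files character vector of file paths
#' @param annotations per-sample annotation data.frame (keyed by `sample_id`)
#' @param sample_ids optional explicit sample ids, parallel to `files`
#' @return a [count_matrix()]
#' @export
read_rcc <- function(files, annotations, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(files))
  }
  per <- lapply(files, function(f) {
    d <- utils::read.table(f, header = FALSE, sep = ",",
                           stringsAsFactors = FALSE)
    if (identical(tolower(as.character(d[1, 1])), "gene")) d <- d[-1, ]
    names(d) <- c("gene", "class", "count")
    d$count <- as.numeric(d$count)
    d
  })
  genes <- per[[1]]$gene
  for (i in seq_along(per)) {
    if (!identical(per[[i]]$gene, genes)) {
      stop_radsig("probe lists differ between RCC files (",
                  files[i], ")")
    }
  }
  counts <- vapply(per, function(d) d$count, numeric(length(genes)))
  dimnames(counts) <- list(genes, sample_ids)
  count_matrix(counts, gene_panel(genes, per[[1]]$class), annotations)
}

write_expr_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
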