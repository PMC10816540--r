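#' Built-in gene signatures
#'
#' Two gene sets drive the default simulation scenarios and the recovery
#' experiments:
#'
#' * `lps_response_genes()` — the 27 inflammatory genes up-regulated in whole
#'   blood after ex vivo LPS stimulation (bacterial-endotoxin response).
#' * `radiation_signature_genes()` — the 31-gene radiation-specific signature
#'   observed across radiotherapy cohorts: 15 up- and 16 down-regulated genes
#'   shared by endometrial, head & neck and conventionally fractionated
#'   prostate cancer patients. CD40 is the single gene shared with the LPS
#'   set (with opposite direction).
#'
#' @return `lps_response_genes()`: a character vector of 27 gene symbols.
#'   `radiation_signature_genes()`: a list with character vectors `up` (15)
#'   and `down` (16).
#' @export
lps_response_genes <- function() {
  c("CCL2", "CXCL2", "CXCL3", "IL6", "MAFF", "IL1A", "IL12B", "CSF3",
    "CXCL9", "CCL3", "C3", "CCL19", "CCL20", "IL1B", "C3AR1", "RIPK2",
    "PTGS2", "TNF", "IRF1", "CD40", "IFNG", "HLA-DRA", "OAS2", "CCL4",
    "CCL22", "CFB", "CXCL10")
}

#' @rdname lps_response_genes
#' @export
radiation_signature_genes <- function() {
  list(
    up = c("ALOX5", "BCL6", "CEBPB", "CFD", "CXCL5", "LIMK1", "MAPK14",
           "MYD88", "NLRP3", "NOD2", "TLR1", "TLR4", "TLR5", "TLR8",
           "TYROBP"),
    down = c("CCR4", "CCR7", "CD40", "CD40LG", "ELK1", "HMGN1", "IL23A",
             "IL7", "IL8", "LTA", "LTB", "MAPKAPK5", "MYC", "PRKCA",
             "TCF4", "TRADD")
  )
}

#' Construct a gene panel
#'
#' A panel maps each probe id to a probe class: `target`, `housekeeping`,
#' `positive_control` or `negative_control`. The default panel is a synthetic
#' stand-in for a 249-target inflammation code set: it contains the 57 gene
#' symbols used by the built-in signatures plus clearly synthetic `SYN###`
#' filler targets, together with 5 housekeeping (`HK_`), 6 positive-control
#' (`POS_`) and 8 negative-control (`NEG_`) probes.
#'
#' @param genes character vector of probe ids. If `NULL`, the default
#'   249-target panel is built.
#' @param class probe class per gene; recycled checks apply. Ignored when
#'   `genes` is `NULL`.
#' @param n_targets,n_housekeeping,n_pos_controls,n_neg_controls panel sizes
#'   used by the default construction.
#' @return a data.frame of class `gene_panel` with columns `gene`, `class`.
#' @examples
#' p <- gene_panel()
#' table(p$class)
#' @export
gene_panel <- function(genes = NULL, class = NULL,
                       n_targets = 249, n_housekeeping = 5,
                       n_pos_controls = 6, n_neg_controls = 8) {
  if (is.null(genes)) {
    sig <- unique(c(lps_response_genes(),
                    radiation_signature_genes()$up,
                    radiation_signature_genes()$down))
    if (n_targets < length(sig)) {
      stop_radsig("n_targets must be at least ", length(sig),
                  " to hold the built-in signature genes")
    }
    fill <- sprintf("SYN%03d", seq_len(n_targets - length(sig)))
    genes <- c(sig, fill)
    class <- rep("target", n_targets)
    genes <- c(genes,
               sprintf("HK_%d", seq_len(n_housekeeping)),
               sprintf("POS_%s", LETTERS[seq_len(n_pos_controls)]),
               sprintf("NEG_%s", LETTERS[seq_len(n_neg_controls)]))
    class <- c(class,
               rep("housekeeping", n_housekeeping),
               rep("positive_control", n_pos_controls),
               rep("negative_control", n_neg_controls))
  }
  class <- match.arg(class, c("target", "housekeeping", "positive_control",
                              "negative_control"), several.ok = TRUE)
  if (length(class) != length(genes)) {
    stop_radsig("panel 'class' must have one entry per gene")
  }
  if (anyDuplicated(genes)) {
    stop_radsig("duplicate gene ids in panel: ",
                paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  out <- data.frame(gene = as.character(genes), class = class,
                    stringsAsFactors = FALSE)
  structure(out, class = c("gene_panel", "data.frame"))
}

#' Probe ids of a given class
#' @param panel a [gene_panel()]
#' @param class probe class to select
#' @return character vector of probe ids
#' @export
panel_genes <- function(panel, class = "target") {
  stopifnot(inherits(panel, "gene_panel"))
  panel$gene[panel$class == class]
}

#' Infer a gene panel from probe-name prefixes
#'
#' Probes named `HK_*`, `POS_*`, `NEG_*` are classed as housekeeping,
#' positive-control and negative-control respectively; all others as targets.
#' @param genes character vector of probe ids
#' @return a [gene_panel()]
#' @export
infer_panel <- function(genes) {
  cls <- rep("target", length(genes))
  cls[startsWith(genes, "HK_")] <- "housekeeping"
  cls[startsWith(genes, "POS_")] <- "positive_control"
  cls[startsWith(genes, "NEG_")] <- "negative_control"
  gene_panel(genes, cls)
}
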