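#' nCounter-style count normalization
#'
#' Applies the standard three-step digital-count normalization, then log2:
#'
#' 1. *Positive-control scaling*: each sample is scaled by
#'    (geometric mean of all samples' positive-control geometric means) /
#'    (this sample's positive-control geometric mean), absorbing global
#'    hybridization/lane effects.
#' 2. *Background thresholding* (optional): per sample, counts below
#'    `mean(negative controls) + 2 * sd(negative controls)` are raised to
#'    that threshold.
#' 3. *Housekeeping scaling*: as step 1 but with the housekeeping-probe
#'    geometric means, absorbing RNA-content differences.
#'
#' Every step is appended to the provenance record of the result.
#'
#' @param raw a [count_matrix()] whose panel contains at least one
#'   positive-control and one housekeeping probe.
#' @param background apply the negative-control background threshold
#'   (default `TRUE`). With `FALSE` the normalization is exactly
#'   scale-equivariant.
#' @return an [expr_matrix()] on the log2 scale.
#' @examples
#' cfg <- scenario_config("variability", seed = 1, n_targets = 40)
#' expr <- normalize_counts(simulate_variability(cfg))
#' expr$provenance
#' @export
normalize_counts <- function(raw, background = TRUE) {
  stopifnot(inherits(raw, "count_matrix"))
  panel <- raw$panel
  pos <- panel$gene[panel$class == "positive_control"]
  hk <- panel$gene[panel$class == "housekeeping"]
  neg <- panel$gene[panel$class == "negative_control"]
  if (length(pos) == 0 || length(hk) == 0) {
    stop_radsig("normalization needs >=1 positive-control and >=1 ",
                "housekeeping probe")
  }
  x <- raw$counts * 1.0
  prov <- character()

  pos_gm <- apply(x[pos, , drop = FALSE], 2, geo_mean)
  if (any(pos_gm == 0)) {
    stop_radsig("positive-control geometric mean of zero in sample(s): ",
                paste(colnames(x)[pos_gm == 0], collapse = ", "))
  }
  pos_factor <- geo_mean(pos_gm) / pos_gm
  x <- sweep(x, 2, pos_factor, "*")
  prov <- c(prov, "positive_control_scaling")

  if (background && length(neg)) {
    nm <- x[neg, , drop = FALSE]
    thr <- colMeans(nm) + 2 * apply(nm, 2, stats::sd)
    x <- pmax(x, rep(thr, each = nrow(x)))
    prov <- c(prov, "negative_control_background")
  }

  hk_gm <- apply(x[hk, , drop = FALSE], 2, geo_mean)
  if (any(hk_gm == 0)) {
    stop_radsig("housekeeping geometric mean of zero in sample(s): ",
                paste(colnames(x)[hk_gm == 0], collapse = ", "))
  }
  hk_factor <- geo_mean(hk_gm) / hk_gm
  x <- sweep(x, 2, hk_factor, "*")
  prov <- c(prov, "housekeeping_scaling", "log2")

  expr_matrix(log2(x), panel, raw$annotations, provenance = prov)
}

#' Row z-score an expression matrix
#'
#' Centers and scales each gene row to mean 0 and sample (n-1) standard
#' deviation 1, the form used for heatmap display and rank-based sample
#' clustering. Constant rows cannot be scaled; they are set to all zeros and
#' flagged in `constant_rows` (and are excluded from clustering distances by
#' default downstream).
#'
#' @param expr an [expr_matrix()] with at least 2 samples.
#' @return an [expr_matrix()] with z-scored values; provenance gains a
#'   `row_zscore` entry.
#' @export
row_zscore <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  if (ncol(v) < 2) stop_radsig("row z-score needs >= 2 samples")
  mu <- rowMeans(v)
  sd <- row_sds(v)
  const <- sd == 0
  sd[const] <- 1
  z <- (v - mu) / sd
  z[const, ] <- 0
  expr_matrix(z, expr$panel, expr$annotations,
              provenance = c(expr$provenance, "row_zscore"),
              constant_rows = rownames(v)[const])
}
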