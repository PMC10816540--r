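#' Spearman correlation distance between samples
#'
#' `d(i, j) = 1 - rho_spearman(column_i, column_j)` with mid-ranks for ties.
#' Anticorrelated samples are maximally distant (d up to 2); the distance is
#' deliberately not based on `|rho|`. Genes flagged as constant rows (see
#' [row_zscore()]) are excluded before computing ranks.
#'
#' @param expr an [expr_matrix()] (typically z-scored) or a numeric matrix,
#'   genes x samples, with >= 3 non-constant genes.
#' @return a symmetric sample x sample distance matrix with zero diagonal.
#' @export
spearman_distance <- function(expr) {
  v <- if (inherits(expr, "expr_matrix")) {
    keep <- setdiff(rownames(expr$values), expr$constant_rows)
    expr$values[keep, , drop = FALSE]
  } else {
    as.matrix(expr)
  }
  if (nrow(v) < 3) stop_radsig("Spearman distance needs >= 3 genes")
  csd <- apply(v, 2, stats::sd)
  if (any(csd == 0)) {
    stop_radsig("constant sample column(s), Spearman correlation undefined: ",
                paste(colnames(v)[csd == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(v, method = "spearman")
  diag(d) <- 0
  d
}

#' Agglomerative complete-linkage clustering
#'
#' Complete (maximum) linkage over a precomputed distance matrix, the
#' standard choice for grouping repeated blood samples by donor. The result
#' carries the merge table, merge heights and leaf labels, plus the
#' underlying `hclust` object.
#'
#' @param dist a symmetric distance matrix (e.g. from
#'   [spearman_distance()]) or a `dist` object, over >= 2 samples.
#' @return an object of class `sample_dendrogram` with elements `merge`,
#'   `height`, `order`, `labels`, `hclust`.
#' @export
hcluster <- function(dist) {
  d <- if (inherits(dist, "dist")) dist else {
    m <- as.matrix(dist)
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
      stop_radsig("distance matrix must be square and symmetric")
    }
    stats::as.dist(m)
  }
  if (attr(d, "Size") < 2) stop_radsig("clustering needs >= 2 samples")
  hc <- stats::hclust(d, method = "complete")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "sample_dendrogram")
}

#' @export
print.sample_dendrogram <- function(x, ...) {
  cat("sample_dendrogram:", length(x$labels), "leaves,",
      length(x$height), "merges (complete linkage)\n")
  invisible(x)
}

#' @export
plot.sample_dendrogram <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

# leaf index sets of every clade (internal node) of an hclust-style merge
clade_leaf_sets <- function(merge) {
  n <- nrow(merge) + 1
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    grab <- function(j) if (j < 0) -j else sets[[j]]
    sets[[i]] <- sort(c(grab(merge[i, 1]), grab(merge[i, 2])))
  }
  sets
}

#' Donor purity of a dendrogram
#'
#' Fraction of donors whose samples form a *pure clade*: some subtree
#' contains all of that donor's samples and nothing else. A purity of 1
#' operationalizes "each individual is identifiable by its expression
#' signature"; singleton donors are pure by definition (a leaf is a clade).
#'
#' @param tree a [hcluster()] result.
#' @param donor_labels donor label per leaf, in leaf (label) order.
#' @return numeric purity in `[0, 1]`.
#' @export
donor_purity <- function(tree, donor_labels) {
  stopifnot(inherits(tree, "sample_dendrogram"))
  n <- length(tree$labels)
  if (length(donor_labels) != n) {
    stop_radsig("donor_labels must have one label per leaf (", n, ")")
  }
  clades <- clade_leaf_sets(tree$merge)
  donors <- unique(donor_labels)
  pure <- vapply(donors, function(d) {
    idx <- sort(which(donor_labels == d))
    if (length(idx) == 1) return(TRUE)
    any(vapply(clades, function(s) identical(s, idx), logical(1)))
  }, logical(1))
  mean(pure)
}

#' Within- vs between-donor distance ratio
#'
#' Mean pairwise distance among samples of the same donor divided by the
#' mean distance between samples of different donors; values well below 1
#' indicate that intra-donor variability is smaller than inter-donor
#' variability.
#'
#' @param dist square distance matrix over samples.
#' @param donor_labels donor label per sample (matrix order).
#' @return list with `within`, `between`, `ratio`.
#' @export
distance_ratio <- function(dist, donor_labels) {
  m <- as.matrix(dist)
  same <- outer(donor_labels, donor_labels, "==")
  ut <- upper.tri(m)
  list(within = mean(m[ut & same]),
       between = mean(m[ut & !same]),
       ratio = mean(m[ut & same]) / mean(m[ut & !same]))
}

#' Newick export of a dendrogram
#' @param tree a [hcluster()] result
#' @return a newick string (requires the ape package)
#' @export
dendrogram_newick <- function(tree) {
  stopifnot(inherits(tree, "sample_dendrogram"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop_radsig("the 'ape' package is required for newick export")
  }
  ape::write.tree(ape::as.phylo(tree$hclust))
}
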