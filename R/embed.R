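#' Empirical-Bayes batch correction
#'
#' Parametric ComBat location/scale adjustment (via the sva package) without
#' covariates: per-gene standardization, empirical-Bayes shrinkage of
#' per-batch gene means and variances, adjustment, and restoration of the
#' pooled location/scale. Single-batch input is returned unchanged.
#'
#' @param expr an [expr_matrix()] or numeric matrix (genes x samples).
#' @param batch batch label per sample; every batch needs >= 2 samples.
#' @return same type as `expr`, batch-adjusted; for an `expr_matrix` the
#'   provenance gains a `combat` entry.
#' @export
combat_adjust <- function(expr, batch = NULL) {
  is_em <- inherits(expr, "expr_matrix")
  v <- if (is_em) expr$values else as.matrix(expr)
  if (is.null(batch) && is_em) batch <- expr$annotations$batch
  if (is.null(batch)) stop_radsig("batch labels are required")
  if (length(batch) != ncol(v)) {
    stop_radsig("batch vector length (", length(batch),
                ") does not match sample count (", ncol(v), ")")
  }
  tab <- table(batch)
  if (any(tab < 2)) {
    stop_radsig("batch(es) with a single sample: ",
                paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (length(tab) == 1) {
    adj <- v
  } else {
    # genes with zero pooled variance break the standardization step
    keep <- row_sds(v) > 0
    adj <- v
    adj[keep, ] <- suppressMessages(
      sva::ComBat(dat = v[keep, , drop = FALSE], batch = factor(batch))
    )
  }
  if (is_em) {
    expr_matrix(adj, expr$panel, expr$annotations,
                provenance = c(expr$provenance, "combat"),
                constant_rows = expr$constant_rows)
  } else {
    adj
  }
}

#' PCA with cumulative-variance component selection
#'
#' Centered principal component analysis over samples; `k` is the smallest
#' number of components whose cumulative explained variance reaches
#' `var_threshold` (99% by default), and the scores of those k components
#' are returned.
#'
#' @param expr an [expr_matrix()] or numeric genes x samples matrix with
#'   >= 2 samples.
#' @param var_threshold required cumulative explained variance, in (0, 1].
#' @return list with `scores` (samples x k), `k`, `explained` (per
#'   component), `cumulative`, `threshold`.
#' @export
pca_select <- function(expr, var_threshold = 0.99) {
  if (var_threshold <= 0 || var_threshold > 1) {
    stop_radsig("var_threshold must be in (0, 1]")
  }
  v <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (ncol(v) < 2) stop_radsig("PCA needs >= 2 samples")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > .Machine$double.eps * max(ev)]
  share <- ev / sum(ev)
  cum <- cumsum(share)
  k <- which(cum >= var_threshold - 1e-12)[1]
  list(scores = pc$x[, seq_len(k), drop = FALSE], k = k,
       explained = share, cumulative = cum, threshold = var_threshold)
}

find_python <- function() {
  py <- Sys.getenv("RADSIG_PYTHON", unset = Sys.which("python"))
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop_radsig("no python interpreter found on PATH")
  py
}

#' Two-dimensional UMAP embedding
#'
#' Nonlinear dimensionality reduction of PCA scores (or any sample-by-
#' feature matrix) to two dimensions via the umap-learn library, which is
#' invoked through the system python. The embedding is treated as an
#' external contract: for a fixed input, seed and hyperparameters the
#' coordinates are deterministic. Because each python process carries JIT
#' start-up cost, a *list* of matrices may be passed to embed several data
#' sets in a single process.
#'
#' @param scores samples x features numeric matrix, or a list of such
#'   matrices (all embedded with the same parameters).
#' @param seed integer random state for UMAP (required).
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15, 0.1);
#'   every input needs at least `n_neighbors + 1` samples.
#' @return for a single matrix: an object of class `rt_embedding` with
#'   `coords` (samples x 2), `seed`, `n_neighbors`, `min_dist`; for a list,
#'   a list of such objects.
#' @export
umap_embed <- function(scores, seed, n_neighbors = 15, min_dist = 0.1) {
  if (missing(seed) || is.null(seed)) {
    stop_radsig("umap_embed requires an integer 'seed'")
  }
  single <- !is.list(scores)
  mats <- if (single) list(scores) else scores
  mats <- lapply(mats, as.matrix)
  for (m in mats) {
    if (nrow(m) < n_neighbors + 1) {
      stop_radsig("UMAP needs at least n_neighbors + 1 = ", n_neighbors + 1,
                  " samples, got ", nrow(m))
    }
    if (!all(is.finite(m))) stop_radsig("scores must be finite")
  }
  dir <- tempfile("umap")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  for (i in seq_along(mats)) {
    utils::write.table(mats[[i]], file.path(dir, sprintf("in_%d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  script <- file.path(dir, "run_umap.py")
  writeLines(c(
    "import sys, numpy as np, umap",
    "d, n, nn, md, seed = sys.argv[1], int(sys.argv[2]), int(sys.argv[3]), float(sys.argv[4]), int(sys.argv[5])",
    "for i in range(1, n + 1):",
    "    X = np.loadtxt(f'{d}/in_{i}.tsv')",
    "    if X.ndim == 1:",
    "        X = X[:, None]",
    "    emb = umap.UMAP(n_neighbors=nn, min_dist=md, random_state=seed,",
    "                    n_jobs=1).fit_transform(X)",
    "    np.savetxt(f'{d}/out_{i}.tsv', emb, delimiter='\\t')"
  ), script)
  res <- suppressWarnings(system2(
    find_python(), c(script, dir, length(mats), n_neighbors,
                     format(min_dist), as.integer(seed)),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0
  if (status != 0) {
    stop_radsig("umap-learn invocation failed:\n",
                paste(utils::tail(res, 5), collapse = "\n"))
  }
  out <- lapply(seq_along(mats), function(i) {
    coords <- as.matrix(utils::read.table(
      file.path(dir, sprintf("out_%d.tsv", i)), sep = "\t"))
    dimnames(coords) <- list(rownames(mats[[i]]), c("umap1", "umap2"))
    structure(list(coords = coords, seed = as.integer(seed),
                   n_neighbors = n_neighbors, min_dist = min_dist),
              class = "rt_embedding")
  })
  if (single) out[[1]] else out
}

#' @export
print.rt_embedding <- function(x, ...) {
  cat("rt_embedding:", nrow(x$coords), "samples (seed", x$seed,
      "| n_neighbors", x$n_neighbors, "| min_dist", x$min_dist, ")\n")
  invisible(x)
}

#' @export
plot.rt_embedding <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) "grey30" else as.integer(factor(labels)) + 1
  plot(x$coords, col = col, pch = 19, xlab = "UMAP 1", ylab = "UMAP 2", ...)
  if (!is.null(labels)) {
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))) + 1, pch = 19,
                     bty = "n")
  }
  invisible(x)
}

#' Batch-corrected PCA + UMAP embedding of an expression matrix
#'
#' Convenience composition of [combat_adjust()], [pca_select()] and
#' [umap_embed()] for visualising pooled pre-treatment samples across
#' collection batches.
#'
#' @param expr an [expr_matrix()].
#' @param batch batch label per sample (default: annotation `batch`).
#' @param var_threshold PCA cumulative-variance threshold (default 0.99).
#' @param seed integer seed for UMAP.
#' @param ... passed to [umap_embed()].
#' @return an `rt_embedding` with extra fields `k` (components used) and
#'   `cumulative_variance` (at k).
#' @export
embed_samples <- function(expr, batch = NULL, var_threshold = 0.99, seed,
                          ...) {
  adj <- combat_adjust(expr, batch)
  pc <- pca_select(adj, var_threshold)
  emb <- umap_embed(pc$scores, seed = seed, ...)
  emb$k <- pc$k
  emb$cumulative_variance <- pc$cumulative[pc$k]
  emb
}

#' Mean silhouette of a 2-group labelling in an embedding
#'
#' Standard silhouette width (Euclidean distances in the embedding) averaged
#' over samples; near-zero values mean the labelling explains none of the
#' embedding geometry.
#'
#' @param coords samples x d coordinate matrix (or `rt_embedding`).
#' @param labels group label per sample (>= 2 groups, each >= 2 samples).
#' @return mean silhouette width in `[-1, 1]`.
#' @export
group_silhouette <- function(coords, labels) {
  if (inherits(coords, "rt_embedding")) coords <- coords$coords
  labels <- as.character(labels)
  n <- nrow(coords)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2) stop_radsig("need >= 2 groups")
  d <- as.matrix(stats::dist(coords))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
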