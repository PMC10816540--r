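# shared fixtures and independent oracles for the test suite

# small-panel config: identical noise model, fewer filler targets, so the
# fast unit tests stay fast
small_config <- function(scenario, seed, ...) {
  scenario_config(scenario, seed, n_targets = 60L, ...)
}

# build an expr_matrix from a plain values matrix (all probes are targets)
make_expr <- function(values, condition = NULL, subject = NULL,
                      timepoint = NULL, protocol = "test", batch = "b1") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  ns <- ncol(values)
  ann <- data.frame(
    sample_id = colnames(values),
    subject = subject %||% colnames(values),
    group = "test",
    condition = condition %||% rep("a", ns),
    timepoint = timepoint %||% rep(NA_character_, ns),
    protocol = protocol,
    batch = batch,
    stringsAsFactors = FALSE
  )
  expr_matrix(values, gene_panel(rownames(values),
                                 rep("target", nrow(values))), ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force agglomerative complete linkage: at every step recompute the
# max inter-cluster distance over all pairs and merge the closest pair
# (lowest indices on ties). Returns the sorted merge heights.
complete_linkage_heights <- function(d) {
  m <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_h <- Inf
    for (j in 2:length(clusters)) {
      for (i in 1:(j - 1)) {
        h <- max(m[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  sort(heights)
}

# independent paired-statistics oracle: explicit sum formulas plus the
# incomplete-beta route to the t-distribution tail (not pt())
oracle_paired <- function(pre, post) {
  n <- length(pre)
  delta <- post - pre
  m <- sum(delta) / n
  s2 <- sum((delta - m)^2) / (n - 1)
  s <- sqrt(s2)
  t <- m / (s / sqrt(n))
  df <- n - 1
  p <- stats::pbeta(df / (df + t^2), df / 2, 0.5)
  list(t = t, df = df, p = p, d = m / s)
}
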