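#' Gaussian mixture model over signal log ratios
#'
#' Fits one-dimensional Gaussian mixtures to per-gene SLR values by
#' expectation-maximization for `K = 1..K_max` components and selects the
#' number of components by the Bayesian Information Criterion
#' `BIC = p * ln(n) - 2 * logL` with `p = 3K - 1` free parameters (lower is
#' better). The component whose mean is nearest zero is the *null*
#' component: it models genes whose response is similar under both
#' conditions, while components with larger and smaller means model up- and
#' down-regulated genes. Ties on `|mean|` resolve toward the heavier
#' component.
#'
#' Each K is fitted with multiple restarts; means are initialized by
#' distance-weighted (k-means++-style) seeding, weights uniformly and all
#' standard deviations at the sample sd. Standard deviations are floored at
#' `sigma_floor_frac * sd(x)` to keep the likelihood bounded. An all-equal
#' input engages the floor and returns a flagged degenerate single-component
#' fit.
#'
#' @param x numeric vector of SLR values, or an `slr_set` from
#'   [compute_slr()].
#' @param K_max largest number of components tried (default 5).
#' @param n_restarts EM restarts per K (default 10).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @param sigma_floor_frac sd floor as a fraction of `sd(x)` (default 1e-3).
#' @param seed integer seed for the restart initializations.
#' @return an object of class `slr_gmm`: the selected fit (`K`, `weights`,
#'   `means`, `sds`, `logL`, `bic`, `n`, `converged`, `null_component`,
#'   `logL_trace`, `degenerate`) plus a `candidates` data.frame with one row
#'   per attempted K and the data in `$x`.
#' @seealso [classify_genes()], [predict.slr_gmm()]
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 0, 0.2), rnorm(30, 2, 0.3))
#' fit <- slr_gmm(x, seed = 1)
#' fit$K
#' coef(fit)
#' @export
slr_gmm <- function(x, K_max = 5, n_restarts = 10, tol = 1e-8,
                    max_iter = 1000, sigma_floor_frac = 1e-3, seed = NULL) {
  values <- if (inherits(x, "slr_set")) x$slr else x
  gene_names <- names(values)
  values <- as.numeric(values)
  if (length(values) < 2) stop_radsig("GMM fitting needs n >= 2 values")
  if (!all(is.finite(values))) stop_radsig("SLR values must be finite")
  n <- length(values)
  s <- stats::sd(values)
  degenerate <- s == 0
  if (degenerate) {
    floor_sd <- max(1e-8, abs(mean(values)) * 1e-8)
    fit <- list(K = 1L, weights = 1, means = mean(values), sds = floor_sd,
                logL = sum(stats::dnorm(values, mean(values), floor_sd,
                                        log = TRUE)),
                n = n, converged = TRUE,
                logL_trace = numeric(0))
    fit$bic <- (3 * 1 - 1) * log(n) - 2 * fit$logL
    cands <- data.frame(K = 1L, logL = fit$logL, bic = fit$bic,
                        converged = TRUE)
  } else {
    floor_sd <- sigma_floor_frac * s
    # short-EM restarts: every restart runs a bounded number of iterations
    # and only the best is polished to full convergence (standard
    # multi-restart EM practice; monotonicity holds within each run)
    fits <- with_seed(seed, lapply(seq_len(K_max), function(K) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        f <- em_gmm1d(values, K, tol = tol,
                      max_iter = min(100L, max_iter),
                      floor_sd = floor_sd, init_sd = s)
        if (is.null(f)) next
        if (is.null(best) || f$logL > best$logL) best <- f
      }
      if (is.null(best)) return(NULL)
      em_gmm1d(values, K, tol = tol, max_iter = max_iter,
               floor_sd = floor_sd, init_sd = s, init = best) %||% best
    }))
    ok <- !vapply(fits, is.null, logical(1))
    for (K in which(!ok)) {
      warning("no converged GMM fit at K = ", K, "; candidate skipped")
    }
    if (!any(ok)) stop_radsig("EM failed to produce any fit")
    cands <- data.frame(
      K = which(ok),
      logL = vapply(fits[ok], `[[`, numeric(1), "logL"),
      converged = vapply(fits[ok], `[[`, logical(1), "converged")
    )
    cands$bic <- (3 * cands$K - 1) * log(n) - 2 * cands$logL
    fit <- fits[ok][[which.min(cands$bic)]]
    fit$bic <- cands$bic[which.min(cands$bic)]
    fit$n <- n
  }
  # null component: mean nearest zero, ties to the larger weight
  ord <- order(abs(fit$means), -fit$weights)
  fit$null_component <- ord[1]
  fit$degenerate <- degenerate
  fit$sigma_floor <- floor_sd
  fit$candidates <- cands[, c("K", "logL", "bic", "converged")]
  fit$x <- stats::setNames(values, gene_names)
  fit$call <- match.call()
  class(fit) <- "slr_gmm"
  fit
}

# One EM run for a 1-D K-component Gaussian mixture (compiled inner loop).
# Returns NULL if the run collapses numerically.
em_gmm1d <- function(x, K, tol, max_iter, floor_sd, init_sd, init = NULL) {
  if (is.null(init)) {
    mu <- kmeanspp_means(x, K)
    w <- rep(1 / K, K)
    sd0 <- rep(max(init_sd, floor_sd), K)
  } else {
    mu <- init$means
    w <- init$weights
    sd0 <- init$sds
  }
  f <- em_gmm1d_cpp(x, mu, w, sd0, tol, as.integer(max_iter), floor_sd)
  if (!f$ok) return(NULL)
  f$ok <- NULL
  f$K <- as.integer(K)
  f
}

# k-means++-style seeding of component means on 1-D data
kmeanspp_means <- function(x, K) {
  mu <- x[sample.int(length(x), 1)]
  d2 <- (x - mu[1])^2
  while (length(mu) < K) {
    if (sum(d2) == 0) {
      mu <- c(mu, x[sample.int(length(x), K - length(mu))])
      break
    }
    nxt <- x[sample.int(length(x), 1, prob = d2)]
    mu <- c(mu, nxt)
    d2 <- pmin(d2, (x - nxt)^2)
  }
  mu[seq_len(K)]
}

#' @export
print.slr_gmm <- function(x, ...) {
  cat("Gaussian mixture over", x$n, "SLR values:",
      x$K, "component(s) selected by BIC\n")
  cat(sprintf("  logL %.3f | BIC %.3f%s\n", x$logL, x$bic,
              if (x$degenerate) " | DEGENERATE (sigma floor engaged)" else ""))
  tab <- coef(x)
  tab <- cbind(tab, null = seq_len(x$K) == x$null_component)
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.slr_gmm <- function(object, ...) {
  cat("Candidate models (BIC = (3K-1) ln n - 2 logL; lower is better):\n")
  print(transform(object$candidates,
                  logL = round(logL, 3), bic = round(bic, 3)),
        row.names = FALSE)
  cat("\nSelected fit:\n")
  print(object)
  thr <- gmm_thresholds(object)
  if (length(thr$breaks)) {
    cat("\nDecision thresholds (max-posterior boundaries):",
        paste(round(thr$breaks, 4), collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
coef.slr_gmm <- function(object, ...) {
  cbind(weight = object$weights, mean = object$means, sd = object$sds)
}

#' @export
logLik.slr_gmm <- function(object, ...) {
  structure(object$logL, df = 3 * object$K - 1, nobs = object$n,
            class = "logLik")
}

#' Posterior component probabilities / classifications for SLR values
#'
#' @param object an [slr_gmm()] fit.
#' @param newdata numeric SLR values (defaults to the fitted data).
#' @param type `"call"` for up/similar/down labels, `"posterior"` for the
#'   n x K posterior matrix, `"component"` for max-posterior component
#'   indices.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.slr_gmm <- function(object, newdata = NULL,
                            type = c("call", "posterior", "component"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  post <- gmm_posterior(object, x)
  if (type == "posterior") return(post)
  comp <- max_posterior_component(object, post)
  if (type == "component") return(comp)
  component_call(object)[comp]
}

gmm_posterior <- function(fit, x) {
  logd <- vapply(seq_len(fit$K), function(k) {
    stats::dnorm(x, fit$means[k], fit$sds[k], log = TRUE) +
      log(fit$weights[k])
  }, numeric(length(x)))
  logd <- matrix(logd, nrow = length(x), ncol = fit$K)
  m <- apply(logd, 1, max)
  post <- exp(logd - (m + log(rowSums(exp(logd - m)))))
  rownames(post) <- names(x)
  post
}

# max-posterior component with ties resolved toward the null component
max_posterior_component <- function(fit, post) {
  comp <- max.col(post, ties.method = "first")
  null_tied <- abs(post[, fit$null_component] -
                     post[cbind(seq_len(nrow(post)), comp)]) < 1e-12
  comp[null_tied] <- fit$null_component
  comp
}

# per-component regulation label relative to the null component's mean
component_call <- function(fit) {
  mu0 <- fit$means[fit$null_component]
  ifelse(seq_len(fit$K) == fit$null_component, "similar",
         ifelse(fit$means > mu0, "up", "down"))
}

# Decision thresholds: SLR points where the max-posterior call changes.
# Located on a fine grid spanning the data, then refined by root finding on
# the two competing components' weighted log densities.
gmm_thresholds <- function(fit, grid_n = 4096) {
  x <- fit$x
  lo <- min(x) - 3 * max(fit$sds)
  hi <- max(x) + 3 * max(fit$sds)
  grid <- seq(lo, hi, length.out = grid_n)
  comp <- max_posterior_component(fit, gmm_posterior(fit, grid))
  chg <- which(diff(comp) != 0)
  breaks <- vapply(chg, function(i) {
    k1 <- comp[i]; k2 <- comp[i + 1]
    f <- function(v) {
      (stats::dnorm(v, fit$means[k1], fit$sds[k1], log = TRUE) +
         log(fit$weights[k1])) -
        (stats::dnorm(v, fit$means[k2], fit$sds[k2], log = TRUE) +
           log(fit$weights[k2]))
    }
    if (f(grid[i]) * f(grid[i + 1]) < 0) {
      stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
    } else {
      (grid[i] + grid[i + 1]) / 2
    }
  }, numeric(1))
  calls <- component_call(fit)
  list(breaks = breaks,
       segment_calls = calls[comp[c(1, chg + 1)]],
       segment_components = comp[c(1, chg + 1)])
}

#' Classify genes from a fitted SLR mixture
#'
#' Assigns every gene to its maximum-posterior mixture component. Genes in
#' the null component are called `"similar"`; genes in components with a
#' larger mean are `"up"`, with a smaller mean `"down"`. Posterior ties are
#' broken toward `"similar"`. The SLR cutpoints at which the call changes
#' (the dashed-line thresholds of a classification scatterplot) are attached
#' as the `"thresholds"` attribute together with per-segment calls.
#'
#' @param fit an [slr_gmm()] fit.
#' @param values optional `slr_set` or named numeric vector to classify
#'   (defaults to the fitted values).
#' @return a data.frame of class `gene_classification` with columns `gene`,
#'   `slr`, `component`, `call`, `max_posterior`, plus attributes
#'   `thresholds` (numeric cutpoints) and `segment_calls`.
#' @export
classify_genes <- function(fit, values = NULL) {
  stopifnot(inherits(fit, "slr_gmm"))
  x <- if (is.null(values)) fit$x
       else if (inherits(values, "slr_set")) values$slr
       else values
  post <- gmm_posterior(fit, x)
  comp <- max_posterior_component(fit, post)
  calls <- component_call(fit)[comp]
  thr <- gmm_thresholds(fit)
  out <- data.frame(
    gene = if (is.null(names(x))) sprintf("g%d", seq_along(x)) else names(x),
    slr = as.numeric(x),
    component = comp,
    call = calls,
    max_posterior = post[cbind(seq_along(x), comp)],
    stringsAsFactors = FALSE
  )
  attr(out, "thresholds") <- thr$breaks
  attr(out, "segment_calls") <- thr$segment_calls
  attr(out, "fit") <- fit
  class(out) <- c("gene_classification", "data.frame")
  out
}

#' @export
print.gene_classification <- function(x, ...) {
  cat("gene_classification:", nrow(x), "genes\n")
  print(table(x$call))
  thr <- attr(x, "thresholds")
  if (length(thr)) {
    cat("thresholds:", paste(round(thr, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn slr_gmm Histogram of the SLR values with the fitted mixture
#'   density and decision thresholds.
#' @param breaks histogram breaks, passed to [graphics::hist()].
#' @export
plot.slr_gmm <- function(x, breaks = 40, ...) {
  graphics::hist(x$x, breaks = breaks, freq = FALSE, col = "grey85",
                 border = "white", xlab = "signal log ratio",
                 main = sprintf("GMM fit (K = %d)", x$K), ...)
  grid <- seq(min(x$x) - 1, max(x$x) + 1, length.out = 512)
  dens <- rowSums(vapply(seq_len(x$K), function(k) {
    x$weights[k] * stats::dnorm(grid, x$means[k], x$sds[k])
  }, numeric(length(grid))))
  graphics::lines(grid, dens, lwd = 2, col = "steelblue")
  thr <- gmm_thresholds(x)$breaks
  if (length(thr)) graphics::abline(v = thr, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
simulate.slr_gmm <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    n <- object$n * nsim
    comp <- sample.int(object$K, n, replace = TRUE, prob = object$weights)
    stats::rnorm(n, object$means[comp], object$sds[comp])
  })
}

#' @export
residuals.slr_gmm <- function(object, ...) {
  post <- gmm_posterior(object, object$x)
  object$x - as.numeric(post %*% object$means)
}
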