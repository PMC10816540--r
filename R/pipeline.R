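#' Write / read a scenario config as flat key-value text
#'
#' Every field of the config is printed, including defaults, so a run
#' directory records the complete generator state with no hidden values.
#'
#' @param config a [scenario_config()]
#' @param path file path
#' @return `write_config()`: the path, invisibly. `read_config()`: a
#'   [scenario_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  lines <- vapply(names(config), function(nm) {
    paste0(nm, " = ", paste(format(config[[nm]], digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_radsig("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  vals <- lapply(vals, parse_val)
  names(vals) <- keys
  if (is.null(vals$scenario)) stop_radsig("config missing 'scenario'")
  if (is.null(vals$seed)) {
    stop_radsig("config missing 'seed' (no silent randomness)")
  }
  args <- vals[setdiff(keys, c("scenario", "seed"))]
  int_fields <- c("n_targets", "n_housekeeping", "n_pos_controls",
                  "n_neg_controls", "n_dilution_points")
  for (f in intersect(names(args), int_fields)) {
    args[[f]] <- as.integer(args[[f]])
  }
  do.call(scenario_config,
          c(list(scenario = vals$scenario, seed = vals$seed), args))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run a complete analysis scenario
#'
#' Simulates the requested scenario, runs its analysis stages in order and
#' writes every intermediate and final table to `out_dir`, together with a
#' full config echo (`config.txt`) and a machine-readable run report
#' (`report.json`) whose headline counts always equal the counts in the
#' referenced output files.
#'
#' Stages per scenario:
#' * `variability`: simulate, normalize, row z-score, Spearman distance,
#'   complete-linkage clustering, donor purity.
#' * `lps_flu`: simulate, normalize, SLRs (LPS, Flu, cross-condition), GMM
#'   fit + BIC selection + max-posterior classification per contrast.
#' * `cancer_cohorts`: simulate every manifest protocol, normalize, paired
#'   DE per protocol, cross-protocol signature integration (SBRT/CyberKnife
#'   protocols excluded from integration).
#' * `qpcr`: simulate Ct + dilution tables, fit standard curves, relative
#'   expression, per-gene per-timepoint decision-tree tests against the
#'   pre-exposure group.
#'
#' @param config a [scenario_config()] or the path to a key-value config
#'   file readable by [read_config()].
#' @param out_dir output directory (created if needed).
#' @return a `run_report` (invisibly written to `report.json`): list with
#'   `scenario`, `seed`, `headline` counts, `outputs` file map, `config`.
#' @export
run_scenario <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "scenario_config")) {
    stop_radsig("config must be a scenario_config or a config file path; ",
                "valid scenarios: variability, lps_flu, cancer_cohorts, qpcr")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  headline <- list()
  pth <- function(f) file.path(out_dir, f)
  write_config(config, pth("config.txt"))
  outputs$config <- "config.txt"

  if (config$scenario == "variability") {
    cm <- simulate_variability(config)
    write_count_matrix(cm, pth("counts.tsv"), pth("annotations.tsv"),
                       pth("panel.tsv"))
    z <- row_zscore(normalize_counts(cm))
    write_expr_matrix(z, pth("zscores.tsv"))
    d <- spearman_distance(z)
    utils::write.table(d, pth("distance.tsv"), sep = "\t", quote = FALSE)
    tree <- hcluster(d)
    write_tsv(data.frame(left = tree$merge[, 1], right = tree$merge[, 2],
                         height = tree$height), pth("merges.tsv"))
    donors <- cm$annotations$subject[match(tree$labels,
                                           cm$annotations$sample_id)]
    purity <- donor_purity(tree, donors)
    ratio <- distance_ratio(d, cm$annotations$subject)
    write_tsv(data.frame(metric = c("donor_purity", "within_distance",
                                    "between_distance", "distance_ratio"),
                         value = c(purity, ratio$within, ratio$between,
                                   ratio$ratio)),
              pth("purity.tsv"))
    outputs <- c(outputs, list(counts = "counts.tsv", zscores = "zscores.tsv",
                               distance = "distance.tsv",
                               merges = "merges.tsv", purity = "purity.tsv"))
    headline <- list(donor_purity = purity, distance_ratio = ratio$ratio)
  } else if (config$scenario == "lps_flu") {
    sim <- simulate_lps_flu(config)
    write_count_matrix(sim$counts, pth("counts.tsv"), pth("annotations.tsv"),
                       pth("panel.tsv"))
    write_tsv(sim$effects, pth("truth.tsv"))
    expr <- normalize_counts(sim$counts)
    slr <- list(
      LPS = compute_slr(expr, "LPS", "Control_LPS", contrast = "LPS"),
      Flu = compute_slr(expr, "Flu", "Control_Flu", contrast = "Flu")
    )
    slr$cross_condition <- cross_condition_slr(slr$LPS, slr$Flu)
    cls <- list()
    gmm_params <- list()
    for (nm in names(slr)) {
      fit <- slr_gmm(slr[[nm]], seed = config$seed)
      cls[[nm]] <- classify_genes(fit)
      gmm_params[[nm]] <- list(
        K = fit$K, weights = fit$weights, means = fit$means, sds = fit$sds,
        logL = fit$logL, bic = fit$bic,
        candidates = fit$candidates,
        thresholds = attr(cls[[nm]], "thresholds"))
    }
    comb <- data.frame(gene = cls$LPS$gene,
                       slr_LPS = cls$LPS$slr, call_LPS = cls$LPS$call,
                       slr_Flu = cls$Flu$slr, call_Flu = cls$Flu$call,
                       slr_cross = cls$cross_condition$slr,
                       call_cross = cls$cross_condition$call,
                       stringsAsFactors = FALSE)
    write_tsv(comb, pth("classification.tsv"))
    jsonlite::write_json(gmm_params, pth("gmm_params.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, list(counts = "counts.tsv", truth = "truth.tsv",
                               classification = "classification.tsv",
                               gmm = "gmm_params.json"))
    headline <- list(
      lps_up = sum(comb$call_LPS == "up"),
      lps_down = sum(comb$call_LPS == "down"),
      flu_up = sum(comb$call_Flu == "up"),
      flu_down = sum(comb$call_Flu == "down"),
      cross_up = sum(comb$call_cross == "up"),
      cross_down = sum(comb$call_cross == "down"))
  } else if (config$scenario == "cancer_cohorts") {
    manifest <- build_manifest()
    tables <- list()
    for (i in seq_len(nrow(manifest))) {
      row <- manifest[i, ]
      cfg_i <- config
      cfg_i$seed <- config$seed + i  # independent draws per protocol
      sim <- simulate_cohort(row, config = cfg_i)
      proto <- row$protocol_name
      write_count_matrix(sim$counts, pth(paste0("counts_", proto, ".tsv")),
                         pth(paste0("annotations_", proto, ".tsv")))
      if (i == 1) write_tsv(sim$effects, pth("truth.tsv"))
      expr <- normalize_counts(sim$counts)
      tables[[proto]] <- cohort_de_table(expr, proto)
      write_tsv(tables[[proto]], pth(paste0("de_", proto, ".tsv")))
    }
    integrated <- integrate_signature(
      tables[setdiff(names(tables), "Prostate_CK")])
    sig_df <- data.frame(
      gene = c(integrated$up, integrated$down),
      direction = rep(c("up", "down"),
                      c(length(integrated$up), length(integrated$down))),
      stringsAsFactors = FALSE)
    write_tsv(sig_df, pth("integrated_signature.tsv"))
    write_tsv(integrated$evidence, pth("evidence.tsv"))
    outputs <- c(outputs, list(truth = "truth.tsv",
                               signature = "integrated_signature.tsv",
                               evidence = "evidence.tsv"))
    headline <- list(signature_up = length(integrated$up),
                     signature_down = length(integrated$down),
                     signature_total = length(integrated$up) +
                       length(integrated$down))
  } else if (config$scenario == "qpcr") {
    sim <- simulate_qpcr(config)
    write_tsv(sim$cts, pth("cts.tsv"))
    write_tsv(sim$dilution, pth("dilution.tsv"))
    write_tsv(sim$truth, pth("truth.tsv"))
    genes <- unique(sim$dilution$gene)
    curves <- lapply(stats::setNames(genes, genes), function(g) {
      fit_standard_curve(sim$dilution[sim$dilution$gene == g, ], gene = g)
    })
    curve_df <- do.call(rbind, lapply(curves, function(cv) {
      data.frame(gene = cv$gene, slope = cv$slope, intercept = cv$intercept,
                 r_squared = cv$r_squared, efficiency = cv$efficiency,
                 qc_pass = cv$qc_pass, stringsAsFactors = FALSE)
    }))
    write_tsv(curve_df, pth("curves.tsv"))
    rel <- relative_expression(sim$cts, curves)
    write_tsv(rel, pth("relative_expression.tsv"))
    tps <- setdiff(unique(rel$timepoint), "pre")
    stats_rows <- list()
    for (g in setdiff(genes, "HPRT1")) {
      pre_vals <- rel$log2_norm[rel$gene == g & rel$timepoint == "pre"]
      for (tp in tps) {
        tp_vals <- rel$log2_norm[rel$gene == g & rel$timepoint == tp]
        ts <- timepoint_test(list(pre = pre_vals, tp = tp_vals),
                             gene = g, timepoint = tp)
        stats_rows[[paste(g, tp)]] <- data.frame(
          gene = g, timepoint = tp, branch = ts$branch, test = ts$test,
          statistic = ts$statistic, p = ts$p, significant = ts$significant,
          stringsAsFactors = FALSE)
      }
    }
    stats_df <- do.call(rbind, stats_rows)
    rownames(stats_df) <- NULL
    write_tsv(stats_df, pth("timepoint_stats.tsv"))
    outputs <- c(outputs, list(cts = "cts.tsv", curves = "curves.tsv",
                               relative = "relative_expression.tsv",
                               stats = "timepoint_stats.tsv"))
    headline <- list(curves_qc_pass = sum(curve_df$qc_pass),
                     significant_tests = sum(stats_df$significant))
  }

  report <- list(scenario = config$scenario, seed = config$seed,
                 headline = headline, outputs = outputs,
                 version = as.character(utils::packageVersion("radsig")))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(c(report, list(dir = out_dir)), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report [", x$scenario, "] seed", x$seed, "\n")
  for (nm in names(x$headline)) {
    cat(sprintf("  %-18s %s\n", nm, format(x$headline[[nm]])))
  }
  invisible(x)
}

# recompute a headline count from the output file it references
recount_headline <- function(dir, report, name) {
  rd <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
  switch(report$scenario,
    lps_flu = {
      cls <- rd(report$outputs$classification)
      switch(name,
        lps_up = sum(cls$call_LPS == "up"),
        lps_down = sum(cls$call_LPS == "down"),
        flu_up = sum(cls$call_Flu == "up"),
        flu_down = sum(cls$call_Flu == "down"),
        cross_up = sum(cls$call_cross == "up"),
        cross_down = sum(cls$call_cross == "down"))
    },
    cancer_cohorts = {
      sig <- rd(report$outputs$signature)
      switch(name,
        signature_up = sum(sig$direction == "up"),
        signature_down = sum(sig$direction == "down"),
        signature_total = nrow(sig))
    },
    variability = {
      pur <- rd(report$outputs$purity)
      switch(name,
        donor_purity = pur$value[pur$metric == "donor_purity"],
        distance_ratio = pur$value[pur$metric == "distance_ratio"])
    },
    qpcr = {
      switch(name,
        curves_qc_pass = sum(rd(report$outputs$curves)$qc_pass == "TRUE" |
                               rd(report$outputs$curves)$qc_pass == TRUE),
        significant_tests =
          sum(rd(report$outputs$stats)$significant == "TRUE" |
                rd(report$outputs$stats)$significant == TRUE))
    })
}

#' Summarize completed runs into a comparison table
#'
#' Reads each run directory's `report.json`, re-derives every headline count
#' from the referenced output file and fails if a report disagrees with its
#' files (integrity check).
#'
#' @param run_dirs character vector of completed [run_scenario()] output
#'   directories (>= 1).
#' @return data.frame with one row per run: `dir`, `scenario`, `seed`, one
#'   column per headline metric.
#' @export
summarize_report <- function(run_dirs) {
  if (length(run_dirs) == 0) stop_radsig("no run directories supplied")
  rows <- lapply(run_dirs, function(d) {
    rp <- file.path(d, "report.json")
    if (!file.exists(rp)) stop_radsig("missing report file: ", rp)
    report <- jsonlite::read_json(rp, simplifyVector = TRUE)
    for (nm in names(report$headline)) {
      actual <- recount_headline(d, report, nm)
      if (!is.null(actual) &&
          !isTRUE(all.equal(as.numeric(actual),
                            as.numeric(report$headline[[nm]]),
                            tolerance = 1e-9))) {
        stop_radsig("integrity error in ", d, ": headline '", nm, "' (",
                    report$headline[[nm]], ") != recount from files (",
                    actual, ")")
      }
    }
    cbind(data.frame(dir = d, scenario = report$scenario,
                     seed = report$seed, stringsAsFactors = FALSE),
          as.data.frame(report$headline))
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
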