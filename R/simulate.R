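#' Scenario configuration for the synthetic-data generator
#'
#' A `scenario_config` fixes every knob of the generator so that a config
#' plus its seed fully determines the simulated data, byte for byte.
#'
#' The count model is log-normal on the log2 scale: each target gene draws a
#' baseline log2 mean uniformly on `baseline_log2_range`, each subject adds a
#' persistent per-gene offset (`biological_sd`, the between-individual
#' "personal inflammatory signature"), each blood draw adds a within-subject
#' occasion offset (`occasion_sd`) and each measurement adds technical noise
#' (`technical_sd`) plus a per-sample global scale shift (`sample_scale_sd`)
#' that the positive-control normalization is designed to remove. Counts are
#' `2^x` rounded to integers with a floor of 1. Setting
#' `count_model = "negbin"` instead draws negative-binomial counts with mean
#' `2^x` and size `nb_size`.
#'
#' Housekeeping probes receive technical noise and the sample scale shift
#' only (they are selected for biological stability); spike-in control
#' probes receive no biology at all.
#'
#' @param scenario one of `"variability"`, `"lps_flu"`, `"cancer_cohorts"`,
#'   `"qpcr"`.
#' @param seed integer seed; mandatory, there is no silent randomness.
#' @param ... overrides for any default field, e.g. `biological_sd = 0.6`,
#'   `lps_effect = 1`, `n_targets = 50`.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("variability", "lps_flu",
                                         "cancer_cohorts", "qpcr"),
                            seed, ...) {
  scenario <- match.arg(scenario)
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop_radsig("scenario_config requires an integer 'seed'")
  }
  cfg <- list(
    scenario = scenario,
    seed = as.integer(seed),
    # noise model
    baseline_log2_range = c(6, 12),
    biological_sd = 0.4,     # between-subject, persistent per gene
    occasion_sd = 0.4 / 3,   # within-subject, per blood draw (1/3 of inter)
    technical_sd = 0.15,     # per measurement
    sample_scale_sd = 0.2,   # per-sample global shift (removed by controls)
    batch_shift_sd = 0.5,    # per-batch per-gene shift (embedding scenario)
    count_model = "lognormal",
    nb_size = 20,
    # effect sizes
    lps_effect = 2.0,
    flu_effect = 0.0,
    cancer_effect = 1.0,
    # panel
    n_targets = 249L,
    n_housekeeping = 5L,
    n_pos_controls = 6L,
    n_neg_controls = 8L,
    # qPCR
    ct_noise_sd = 0.1,
    qpcr_patient_sd = 0.5,
    qpcr_hprt_sd = 0.15,
    qpcr_log2fc = 1.0,
    qpcr_base_quantity = 1e-6,
    dilution_range = c(3.2e-4, 8.2e-10),
    n_dilution_points = 7L,
    curve_slope = -1 / log10(2),  # perfect doubling, -3.3219 Ct/log10
    curve_intercept = 4.0
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_radsig("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  sds <- c("biological_sd", "occasion_sd", "technical_sd", "sample_scale_sd",
           "batch_shift_sd", "ct_noise_sd", "qpcr_patient_sd", "qpcr_hprt_sd")
  if (any(unlist(cfg[sds]) < 0)) stop_radsig("all sd parameters must be >= 0")
  cfg$count_model <- match.arg(cfg$count_model, c("lognormal", "negbin"))
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config:", x$scenario, "(seed", paste0(x$seed, ")"), "\n")
  cat("  noise: biological", x$biological_sd, "| occasion", round(x$occasion_sd, 4),
      "| technical", x$technical_sd, "| sample-scale", x$sample_scale_sd, "\n")
  cat("  panel:", x$n_targets, "targets +", x$n_housekeeping, "HK +",
      x$n_pos_controls, "POS +", x$n_neg_controls, "NEG\n")
  invisible(x)
}

scenario_panel <- function(config) {
  gene_panel(n_targets = config$n_targets,
             n_housekeeping = config$n_housekeeping,
             n_pos_controls = config$n_pos_controls,
             n_neg_controls = config$n_neg_controls)
}

# Draw per-probe baseline log2 means. Positive controls form a fixed spike
# ladder; negative controls sit near background.
draw_baselines <- function(panel, config) {
  mu <- numeric(nrow(panel))
  names(mu) <- panel$gene
  tg <- panel$class == "target"
  mu[tg] <- stats::runif(sum(tg), config$baseline_log2_range[1],
                         config$baseline_log2_range[2])
  hk <- panel$class == "housekeeping"
  mu[hk] <- stats::runif(sum(hk), 8, 12)
  pos <- which(panel$class == "positive_control")
  mu[pos] <- seq(15, by = -2, length.out = length(pos))
  mu[panel$class == "negative_control"] <- 2.5
  mu
}

# Core count sampler shared by all expression scenarios.
#   subject_of : per-sample subject index (persistent offsets)
#   shift      : genes x samples planted log2 shifts (targets only)
#   donor_sd   : sd of the persistent per-subject offsets
sim_counts <- function(panel, annotations, shift, config,
                       donor_sd = config$biological_sd) {
  ng <- nrow(panel)
  ns <- nrow(annotations)
  mu <- draw_baselines(panel, config)
  tg <- panel$class == "target"
  hk_or_tg <- panel$class %in% c("target", "housekeeping")
  subjects <- unique(annotations$subject)
  subj_off <- matrix(0, ng, length(subjects),
                     dimnames = list(panel$gene, subjects))
  subj_off[tg, ] <- stats::rnorm(sum(tg) * length(subjects), 0, donor_sd)
  occ <- matrix(0, ng, ns)
  occ[tg, ] <- stats::rnorm(sum(tg) * ns, 0, config$occasion_sd)
  tech <- matrix(stats::rnorm(ng * ns, 0, config$technical_sd), ng, ns)
  sshift <- stats::rnorm(ns, 0, config$sample_scale_sd)
  log2x <- mu + subj_off[, annotations$subject, drop = FALSE] + occ + tech +
    rep(sshift, each = ng) + shift
  counts <- if (config$count_model == "negbin") {
    matrix(stats::rnbinom(ng * ns, mu = 2^log2x, size = config$nb_size),
           ng, ns)
  } else {
    round(2^log2x)
  }
  counts[counts < 1] <- 1
  dimnames(counts) <- list(panel$gene, annotations$sample_id)
  count_matrix(counts, panel, annotations)
}

#' Simulate a paired pre/post radiotherapy cohort
#'
#' Generates one pre-exposure and one post-exposure (24 h after the last
#' fraction) blood sample per patient for a single protocol row of a
#' [build_manifest()] table. Post samples have their target-gene log2 means
#' shifted by the planted effects; housekeeping and control probes are never
#' shifted.
#'
#' @param manifest_row one row of a [build_manifest()] table.
#' @param effects an [effect_manifest()] covering all panel target genes, or
#'   `NULL` for the default planted radiation signature
#'   (`radiation_signature_genes()` at +/- `config$cancer_effect` log2).
#' @param config a [scenario_config()] (scenario `"cancer_cohorts"`).
#' @return list with elements `counts` (a [count_matrix()]) and `effects`
#'   (the [effect_manifest()] used).
#' @examples
#' cfg <- scenario_config("cancer_cohorts", seed = 1)
#' sim <- simulate_cohort(build_manifest()[1, ], config = cfg)
#' dim(sim$counts)
#' @export
simulate_cohort <- function(manifest_row, effects = NULL, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (nrow(manifest_row) != 1) stop_radsig("manifest_row must be one row")
  panel <- scenario_panel(config)
  if (is.null(effects)) {
    sig <- radiation_signature_genes()
    effects <- planted_effects(panel, up = sig$up, down = sig$down,
                               effect = config$cancer_effect)
  }
  targets <- panel_genes(panel, "target")
  unknown <- setdiff(effects$gene, targets)
  if (length(unknown)) {
    stop_radsig("effects reference unknown gene(s): ",
                paste(unknown, collapse = ", "))
  }
  if (!setequal(effects$gene, targets)) {
    stop_radsig("effects must cover every panel target gene")
  }
  proto <- manifest_row$protocol_name
  n <- manifest_row$n_patients
  subj <- sprintf("%s_P%02d", proto, seq_len(n))
  ann <- data.frame(
    sample_id = c(paste0(subj, "_pre"), paste0(subj, "_post")),
    subject = rep(subj, 2),
    group = "cancer",
    condition = rep(c("pre", "post"), each = n),
    timepoint = rep(c("pre", "post"), each = n),
    protocol = proto,
    batch = manifest_row$batch %||% proto,
    stringsAsFactors = FALSE
  )
  lfc <- stats::setNames(effects$true_log2fc, effects$gene)
  shift <- matrix(0, nrow(panel), nrow(ann),
                  dimnames = list(panel$gene, ann$sample_id))
  shift[names(lfc), ann$timepoint == "post"] <- lfc
  cm <- with_seed(config$seed, sim_counts(panel, ann, shift, config))
  list(counts = cm, effects = effects)
}

#' Simulate the paired LPS / flu-vaccine donor experiment
#'
#' Four arms (`LPS`, `Control_LPS`, `Flu`, `Control_Flu`) on the same healthy
#' donors, donor-paired: each donor keeps one persistent expression profile
#' across all four samples. The planted gene set is shifted by
#' `config$lps_effect` in the LPS arm only; the flu arm receives
#' `config$flu_effect` (zero by default, emulating an undetectable
#' vaccination response).
#'
#' @param config a [scenario_config()] (scenario `"lps_flu"`).
#' @param planted_up character vector of responsive genes, a subset of the
#'   panel targets. Default: the 27-gene LPS response set.
#' @param n_donors number of paired donors (default 7, minimum 2).
#' @return list with `counts` (a [count_matrix()]) and `effects` (an
#'   [effect_manifest()] with one row per gene and contrast).
#' @export
simulate_lps_flu <- function(config, planted_up = lps_response_genes(),
                             n_donors = 7) {
  stopifnot(inherits(config, "scenario_config"))
  if (n_donors < 2) {
    stop_radsig("n_donors must be >= 2 (pairing undefined otherwise)")
  }
  panel <- scenario_panel(config)
  targets <- panel_genes(panel, "target")
  unknown <- setdiff(planted_up, targets)
  if (length(unknown)) {
    stop_radsig("planted genes not in panel: ", paste(unknown, collapse = ", "))
  }
  donors <- sprintf("donor%02d", seq_len(n_donors))
  arms <- c("LPS", "Control_LPS", "Flu", "Control_Flu")
  ann <- data.frame(
    sample_id = paste0(rep(donors, times = length(arms)), "_",
                       rep(arms, each = n_donors)),
    subject = rep(donors, times = length(arms)),
    group = "healthy",
    condition = rep(arms, each = n_donors),
    timepoint = NA_character_,
    protocol = "lps_flu",
    batch = "HD",
    stringsAsFactors = FALSE
  )
  shift <- matrix(0, nrow(panel), nrow(ann),
                  dimnames = list(panel$gene, ann$sample_id))
  shift[planted_up, ann$condition == "LPS"] <- config$lps_effect
  if (config$flu_effect != 0) {
    shift[planted_up, ann$condition == "Flu"] <- config$flu_effect
  }
  cm <- with_seed(config$seed, sim_counts(panel, ann, shift, config))
  eff_lps <- planted_effects(panel, up = planted_up,
                             effect = config$lps_effect, contrast = "LPS")
  eff_flu <- if (config$flu_effect > 0) {
    planted_effects(panel, up = planted_up, effect = config$flu_effect,
                    contrast = "Flu")
  } else {
    planted_effects(panel, contrast = "Flu")
  }
  effects <- rbind(eff_lps, eff_flu)
  class(effects) <- class(eff_lps)
  list(counts = cm, effects = effects)
}

#' Simulate repeated sampling of healthy donors
#'
#' Emulates the donor-variability design: each donor is bled on several
#' occasions weeks apart. Per-donor gene offsets (sd `config$biological_sd`)
#' persist across occasions, while each occasion adds smaller within-donor
#' variation (`config$occasion_sd`) - the structure under which unsupervised
#' clustering groups samples by donor.
#'
#' @param config a [scenario_config()] (scenario `"variability"`).
#' @param n_donors,n_occasions design size (defaults 4 donors x 3 occasions;
#'   at least 2 occasions required).
#' @return a [count_matrix()]; donor and occasion are in the annotations.
#' @export
simulate_variability <- function(config, n_donors = 4, n_occasions = 3) {
  stopifnot(inherits(config, "scenario_config"))
  if (n_occasions < 2) stop_radsig("n_occasions must be >= 2")
  if (config$biological_sd <= config$occasion_sd) {
    warning("inter-donor sd does not exceed intra-donor sd; ",
            "donor clustering is not expected to be recoverable")
  }
  panel <- scenario_panel(config)
  donors <- sprintf("donor%02d", seq_len(n_donors))
  occ <- sprintf("occ%d", seq_len(n_occasions))
  ann <- data.frame(
    sample_id = paste0(rep(donors, each = n_occasions), "_",
                       rep(occ, times = n_donors)),
    subject = rep(donors, each = n_occasions),
    group = "healthy",
    condition = "baseline",
    timepoint = rep(occ, times = n_donors),
    protocol = "variability",
    batch = "HD",
    stringsAsFactors = FALSE
  )
  shift <- matrix(0, nrow(panel), nrow(ann),
                  dimnames = list(panel$gene, ann$sample_id))
  with_seed(config$seed, sim_counts(panel, ann, shift, config))
}

qpcr_default_genes <- function() {
  c("BCL6", "MYD88", "MYC", "IL7", "CCR4", "CCR7")
}

#' Simulate MQRT-PCR Ct tables with standard-curve dilution series
#'
#' Generates triplicate Ct values per gene, patient and timepoint together
#' with a serial-dilution calibration series per gene. Each patient carries a
#' persistent log2 expression offset; planted log2 fold changes (relative to
#' the pre-exposure timepoint) shift the true transcript quantity, which is
#' converted to Ct through the true standard curve plus Gaussian Ct noise.
#'
#' By default the up-regulated signature genes BCL6 and MYD88 are planted at
#' `+config$qpcr_log2fc` and MYC, IL7, CCR4 and CCR7 at `-config$qpcr_log2fc`
#' at the two late timepoints (`last_fraction`, `post_1mo`).
#'
#' @param config a [scenario_config()] (scenario `"qpcr"`).
#' @param curve_truth list with `slope` (Ct per log10 quantity, negative) and
#'   `intercept`; default from the config (perfect doubling, -3.3219).
#' @param design list with `n_patients` and `timepoints`.
#' @param genes target genes to simulate (HPRT1 is always added as the
#'   internal control).
#' @param truth optional data.frame `gene`, `timepoint`, `true_log2fc`
#'   overriding the default planted effects.
#' @return list with `cts` (long table: gene, patient, timepoint, replicate,
#'   ct, hprt_ct), `dilution` (gene, quantity, ct), `truth`, `curve_truth`.
#' @export
simulate_qpcr <- function(config, curve_truth = NULL, design = NULL,
                          genes = qpcr_default_genes(), truth = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  curve_truth <- curve_truth %||% list(slope = config$curve_slope,
                                       intercept = config$curve_intercept)
  if (curve_truth$slope >= 0) stop_radsig("curve slope must be negative")
  design <- design %||% list(n_patients = 10,
                             timepoints = c("pre", "24h", "48h", "1wk",
                                            "last_fraction", "post_1mo"))
  tps <- design$timepoints
  if (tps[1] != "pre") stop_radsig("first design timepoint must be 'pre'")
  dr <- config$dilution_range
  if (any(dr <= 0) || config$qpcr_base_quantity <= 0) {
    stop_radsig("quantities must be positive")
  }
  if (is.null(truth)) {
    late <- intersect(c("last_fraction", "post_1mo"), tps)
    dirn <- ifelse(genes %in% c("MYC", "IL7", "CCR4", "CCR7"), -1, 1)
    truth <- expand.grid(gene = genes, timepoint = tps,
                         stringsAsFactors = FALSE)
    truth$true_log2fc <- ifelse(truth$timepoint %in% late,
                                dirn[match(truth$gene, genes)] *
                                  config$qpcr_log2fc, 0)
  }
  with_seed(config$seed, {
    # calibration: log-spaced dilution points between the stated endpoints
    qs <- 10^seq(log10(dr[1]), log10(dr[2]),
                 length.out = config$n_dilution_points)
    dilution <- do.call(rbind, lapply(c(genes, "HPRT1"), function(g) {
      data.frame(gene = g, quantity = qs,
                 ct = curve_truth$intercept + curve_truth$slope * log10(qs) +
                   stats::rnorm(length(qs), 0, config$ct_noise_sd),
                 stringsAsFactors = FALSE)
    }))
    n <- design$n_patients
    pats <- sprintf("pat%02d", seq_len(n))
    grid <- expand.grid(gene = genes, patient = pats, timepoint = tps,
                        stringsAsFactors = FALSE)
    pat_off <- matrix(stats::rnorm(length(genes) * n, 0,
                                   config$qpcr_patient_sd),
                      length(genes), n, dimnames = list(genes, pats))
    hprt_off <- stats::setNames(stats::rnorm(n, 0, config$qpcr_hprt_sd), pats)
    lfc <- truth$true_log2fc[match(paste(grid$gene, grid$timepoint),
                                   paste(truth$gene, truth$timepoint))]
    q_target <- config$qpcr_base_quantity *
      2^(pat_off[cbind(grid$gene, grid$patient)] + lfc)
    q_hprt <- config$qpcr_base_quantity * 2^hprt_off[grid$patient]
    rows <- grid[rep(seq_len(nrow(grid)), each = 3), ]
    rows$replicate <- rep(1:3, nrow(grid))
    qt <- rep(q_target, each = 3)
    qh <- rep(q_hprt, each = 3)
    rows$ct <- curve_truth$intercept + curve_truth$slope * log10(qt) +
      stats::rnorm(nrow(rows), 0, config$ct_noise_sd)
    rows$hprt_ct <- curve_truth$intercept + curve_truth$slope * log10(qh) +
      stats::rnorm(nrow(rows), 0, config$ct_noise_sd)
    rownames(rows) <- NULL
    list(cts = rows, dilution = dilution, truth = truth,
         curve_truth = curve_truth)
  })
}
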