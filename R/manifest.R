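#' Radiotherapy cohort manifest
#'
#' Builds the table of treatment protocols used by the cohort simulations:
#' one row per protocol with patient count, dose per fraction, number of
#' fractions and blood-sampling timepoints. The total dose is always
#' recomputed as `dose_per_fraction * n_fractions`, never copied from input.
#'
#' The default manifest describes five protocols (63 patients in total):
#' endometrium (10 patients, 1.8 Gy x 25), head & neck treated at two centres
#' (8 patients, 2 Gy x 25; 23 patients, 1.8 Gy x 30 - representative
#' schedules within the clinically used ranges), conventionally fractionated
#' IMRT prostate (11 patients, 2 Gy x 39 = 78 Gy) and CyberKnife SBRT
#' prostate (11 patients, 7.25 Gy x 5 = 36.25 Gy). CyberKnife patients are
#' excluded from signature integration by default because of the radically
#' different fractionation.
#'
#' @param source `"default"` for the built-in manifest, `"table"` to validate
#'   a user-supplied data.frame.
#' @param table when `source = "table"`: a data.frame with columns
#'   `protocol_name`, `n_patients`, `dose_per_fraction`, `n_fractions` and
#'   optionally `timepoints` (list column) and `batch`.
#' @return data.frame of class `cohort_manifest` with the five protocol
#'   columns plus computed `total_dose`, a `timepoints` list column and a
#'   `batch` label.
#' @examples
#' m <- build_manifest()
#' sum(m$n_patients)          # 63
#' m$total_dose               # 45 50 54 78 36.25
#' @export
build_manifest <- function(source = c("default", "table"), table = NULL) {
  source <- match.arg(source)
  tp6 <- c("pre", "24h", "48h", "1wk", "last_fraction", "post_1mo")
  if (source == "default") {
    table <- data.frame(
      protocol_name = c("Endometrium", "HeadNeck_FNHK", "HeadNeck_MSCI",
                        "Prostate_IMRT", "Prostate_CK"),
      n_patients = c(10L, 8L, 23L, 11L, 11L),
      dose_per_fraction = c(1.8, 2.0, 1.8, 2.0, 7.25),
      n_fractions = c(25L, 25L, 30L, 39L, 5L),
      batch = c("FNHK", "FNHK", "MSCI", "MSCI", "MSCI"),
      stringsAsFactors = FALSE
    )
    table$timepoints <- rep(list(tp6), nrow(table))
  }
  if (is.null(table) || nrow(table) == 0) {
    stop_radsig("manifest table is empty")
  }
  need <- c("protocol_name", "n_patients", "dose_per_fraction", "n_fractions")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop_radsig("manifest table missing column(s): ",
                paste(miss, collapse = ", "))
  }
  if (is.null(table$timepoints)) table$timepoints <- rep(list(tp6), nrow(table))
  if (is.null(table$batch)) table$batch <- table$protocol_name
  if (any(table$n_patients < 1)) {
    stop_radsig("n_patients must be >= 1 for every protocol")
  }
  if (any(table$n_fractions <= 0) || any(table$dose_per_fraction <= 0)) {
    stop_radsig("doses and fraction counts must be positive")
  }
  for (tps in table$timepoints) {
    if (length(tps) == 0 || anyDuplicated(tps)) {
      stop_radsig("timepoints must be non-empty and unique")
    }
  }
  table$total_dose <- table$dose_per_fraction * table$n_fractions
  rownames(table) <- NULL
  structure(table, class = c("cohort_manifest", "data.frame"))
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat("Cohort manifest:", nrow(x), "protocol(s),",
      sum(x$n_patients), "patients\n")
  show <- x[, c("protocol_name", "n_patients", "dose_per_fraction",
                "n_fractions", "total_dose")]
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}
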