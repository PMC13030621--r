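# Concurrent-validity metrics between paired angle curves and their
# cohort-level aggregation.

#' Root mean square error between two angle cycles
#'
#' @param a,b Angle cycles ([angle_cycle()] or bare 101-sample numerics) of
#'   the same outcome.
#' @return RMSE in degrees.
#' @export
#' @examples
#' rmse(rep(1, 101), rep(0, 101))  # 1
rmse <- function(a, b) {
  check_same_outcome(a, b)
  d <- as_samples(a, "a") - as_samples(b, "b")
  sqrt(mean(d^2))
}

#' RMSE centered at the mean
#'
#' RMSE after removing each curve's own cycle mean; isolates waveform error
#' from the constant between-system offset (a pure offset yields 0).
#'
#' @inheritParams rmse
#' @return Centered RMSE in degrees.
#' @export
centered_rmse <- function(a, b) {
  check_same_outcome(a, b)
  sa <- as_samples(a, "a"); sb <- as_samples(b, "b")
  d <- (sa - mean(sa)) - (sb - mean(sb))
  sqrt(mean(d^2))
}

#' Pearson correlation between two angle cycles
#'
#' @inheritParams rmse
#' @return Correlation coefficient over the 101 points.
#' @export
pearson_cc <- function(a, b) {
  check_same_outcome(a, b)
  sa <- as_samples(a, "a"); sb <- as_samples(b, "b")
  if (sd(sa) < 1e-12 || sd(sb) < 1e-12) {
    abort_data("undefined correlation: constant curve", "gv_undefined_cc")
  }
  cor(sa, sb)
}

#' Absolute difference in range of motion
#' @inheritParams rmse
#' @return |ROM(a) - ROM(b)| in degrees.
#' @export
delta_rom <- function(a, b) {
  check_same_outcome(a, b)
  sa <- as_samples(a, "a"); sb <- as_samples(b, "b")
  abs((max(sa) - min(sa)) - (max(sb) - min(sb)))
}

#' RMSE relative to the reference curve amplitude
#'
#' @param a Test (IMU) cycle.
#' @param b Reference (OPTO) cycle; its range of motion is the denominator.
#' @return 100 * RMSE / ROM(b), percent.
#' @export
relative_rmse <- function(a, b) {
  check_same_outcome(a, b)
  sb <- as_samples(b, "b")
  amp <- max(sb) - min(sb)
  if (amp <= 1) {
    abort_data(sprintf(
      "degenerate amplitude: reference range of motion %.3f deg is <= 1 deg", amp),
      "gv_degenerate_amplitude")
  }
  100 * rmse(a, b) / amp
}

#' Interpret a correlation coefficient with Altman's bands
#'
#' poor `< 0.20`, fair `[0.20, 0.40)`, moderate `[0.40, 0.60)`,
#' good `[0.60, 0.80)`, very good `>= 0.80` (inclusive lower bounds).
#'
#' @param cc Correlation value(s) in `[-1, 1]`.
#' @return Character vector of band labels.
#' @export
interpret_cc_altman <- function(cc) {
  if (any(!is.finite(cc)) || any(cc < -1) || any(cc > 1)) {
    abort_validation("correlation values must lie in [-1, 1]")
  }
  as.character(cut(cc, breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf),
                   labels = c("poor", "fair", "moderate", "good", "very good"),
                   right = FALSE))
}

## ---- table-level computation -----------------------------------------------

# Per-pair metrics for every matched OPTO/IMU cycle of session 1.
# Returns one row per cycle pair; cc is NA (logged) for constant curves and
# relative_rmse is NA when the reference amplitude is degenerate.
pair_metrics <- function(table) {
  dt <- as.data.table(cohort_table(table))[session == 1L]
  key <- setdiff(KEY_COLS, "system")
  opto <- dt[system == "OPTO"]; imu <- dt[system == "IMU"]
  if (!nrow(opto) || !nrow(imu)) {
    abort_pairing("paired validity analysis needs cycles from both systems")
  }
  setkeyv(opto, key); setkeyv(imu, key)
  if (nrow(opto) != nrow(imu) ||
      !identical(opto[, key, with = FALSE], imu[, key, with = FALSE])) {
    abort_pairing("OPTO and IMU cycles are not one-to-one matched on their keys")
  }
  O <- sample_matrix(opto); I <- sample_matrix(imu)
  D <- I - O
  msq <- rowMeans(D^2)
  md <- rowMeans(D)
  out <- opto[, key, with = FALSE]
  out[, rmse := sqrt(msq)]
  out[, centered_rmse := sqrt(pmax(msq - md^2, 0))]
  sd_o <- apply(O, 1L, sd); sd_i <- apply(I, 1L, sd)
  covio <- rowMeans(O * I) - rowMeans(O) * rowMeans(I)
  cc <- covio / (sd_o * sd_i) * N_SAMPLES / (N_SAMPLES - 1)
  flat <- sd_o < 1e-12 | sd_i < 1e-12
  cc[flat] <- NA_real_
  if (any(flat)) {
    gv_log("validity", sprintf("excluded %d pair(s) with undefined correlation",
                               sum(flat)))
  }
  out[, cc := pmin(pmax(cc, -1), 1)]
  rom_o <- apply(O, 1L, function(x) max(x) - min(x))
  rom_i <- apply(I, 1L, function(x) max(x) - min(x))
  out[, delta_rom := abs(rom_o - rom_i)]
  rel <- 100 * sqrt(msq) / rom_o
  rel[rom_o <= 1] <- NA_real_
  out[, relative_rmse := rel]
  out[]
}

#' Summarize concurrent validity over a paired cohort
#'
#' Validity metrics (RMSE, centered RMSE, Pearson correlation, absolute
#' difference in range of motion, relative RMSE) are computed cycle by cycle
#' on session-1 pairs, averaged over each subject's cycles and sides, then
#' summarized per group and outcome as the mean across subjects with a 95\%
#' t-interval half-width. Group RMSE means are flagged against the clinical
#' acceptability threshold (strictly below `config$clinical_threshold`).
#'
#' @param table A [cohort_table()] with matched OPTO/IMU cycles.
#' @param config An [analysis_config()].
#' @return A list of class `validity_summary`: `by_pair` (per cycle pair),
#'   `by_subject` (subject-level means), `by_outcome` (group x outcome means,
#'   CI half-widths and acceptability flags) and `overall` (per-group means
#'   across the outcomes).
#' @export
summarize_validity <- function(table, config = analysis_config()) {
  pairs <- pair_metrics(table)
  metrics <- c("rmse", "centered_rmse", "cc", "delta_rom", "relative_rmse")
  by_subject <- pairs[, lapply(.SD, mean, na.rm = TRUE),
                      by = .(subject_id, group, outcome), .SDcols = metrics]
  half_ci <- function(x) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 2L) return(NA_real_)
    qt(0.975, n - 1L) * sd(x) / sqrt(n)
  }
  by_outcome <- by_subject[, c(
    lapply(.SD, mean, na.rm = TRUE),
    .(rmse_ci = half_ci(rmse), n_subjects = .N)
  ), by = .(group, outcome), .SDcols = metrics]
  if (any(by_outcome$n_subjects < 2L)) {
    warning("group(s) with fewer than 2 subjects: confidence intervals omitted",
            call. = FALSE)
  }
  by_outcome[, acceptable := rmse < config$clinical_threshold]
  overall <- by_outcome[, lapply(.SD, mean, na.rm = TRUE),
                        by = group, .SDcols = metrics]
  structure(list(by_pair = pairs, by_subject = by_subject,
                 by_outcome = by_outcome[], overall = overall[],
                 clinical_threshold = config$clinical_threshold),
            class = "validity_summary")
}

#' @export
print.validity_summary <- function(x, ...) {
  cat("<validity_summary> group means across outcomes (deg / percent):\n")
  print(x$overall, digits = 3)
  invisible(x)
}

#' Correlate per-outcome RMSE with the reference Gait Profile Score
#'
#' Tests whether the between-system error grows with the level of gait
#' deviation: for each outcome, the subject-level mean RMSE is correlated
#' (Pearson) with the subject's side-averaged reference GPS.
#'
#' @param table A paired [cohort_table()].
#' @param gps_opto A data.frame with columns `subject_id` and `gps`
#'   (side-mean reference GPS per subject, degrees), e.g. from [gps_table()].
#' @return A `data.table` with columns `outcome`, `cc`, `p_value`, `band`.
#' @export
rmse_vs_gps_correlation <- function(table, gps_opto) {
  if (!is.data.frame(gps_opto) ||
      !all(c("subject_id", "gps") %in% names(gps_opto))) {
    abort_validation("'gps_opto' must have columns subject_id and gps")
  }
  subj <- summarize_validity(table)$by_subject
  merged <- merge(subj[, .(subject_id, outcome, rmse)],
                  as.data.table(gps_opto)[, .(subject_id, gps)],
                  by = "subject_id")
  if (length(unique(merged$subject_id)) < 3L) {
    abort_validation("at least 3 subjects are required for the RMSE-GPS correlation")
  }
  res <- merged[, {
    if (sd(rmse) < 1e-12 || sd(gps) < 1e-12) {
      abort_data(sprintf("undefined correlation: constant RMSE or GPS for %s",
                         outcome[1L]), "gv_undefined_cc")
    }
    ct <- cor.test(rmse, gps, method = "pearson")
    .(cc = unname(ct$estimate), p_value = ct$p.value)
  }, by = outcome]
  res[, band := interpret_cc_altman(cc)]
  res[]
}
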