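# Gait Profile Score: normative banks, gait variable scores, per-side GPS.

#' Build a system-specific normative bank
#'
#' The mean normal data of one measuring system: for each of the nine GPS
#' angles, the pointwise mean across all session-1 cycles (both sides
#' pooled) of the asymptomatic (AS) group measured with that system.
#'
#' @param table A [cohort_table()] containing AS subjects.
#' @param system `"OPTO"` or `"IMU"`.
#' @param gps_outcomes The GPS angle set (default [GPS_OUTCOMES]).
#' @return A list of class `normative_bank`: `system` and `curves`
#'   (9 x 101 matrix, rows named by outcome, degrees).
#' @export
build_normative_bank <- function(table, system = c("OPTO", "IMU"),
                                 gps_outcomes = GPS_OUTCOMES) {
  system <- match.arg(system)
  dt <- as.data.table(cohort_table(table))
  sys <- system
  as_rows <- dt[group == "AS" & session == 1L & system == sys]
  if (!nrow(as_rows)) {
    abort_data("no asymptomatic (AS) session-1 cycles for this system")
  }
  curves <- matrix(NA_real_, nrow = length(gps_outcomes), ncol = N_SAMPLES,
                   dimnames = list(gps_outcomes, SAMPLE_COLS))
  for (o in gps_outcomes) {
    rows <- as_rows[outcome == o]
    if (!nrow(rows)) {
      abort_data(sprintf("normative bank coverage error: no AS cycles for outcome %s",
                         o))
    }
    curves[o, ] <- colMeans(sample_matrix(rows))
  }
  structure(list(system = system, curves = curves, n_subjects =
                   length(unique(as_rows$subject_id))),
            class = "normative_bank")
}

#' @export
print.normative_bank <- function(x, ...) {
  cat(sprintf("<normative_bank> %s system, %d outcomes, %d AS subjects\n",
              x$system, nrow(x$curves), x$n_subjects))
  invisible(x)
}

#' Gait variable score of one curve against a normative mean curve
#'
#' Root mean square distance between a subject's curve and the normative
#' mean curve across the gait cycle.
#'
#' @param cycle An [angle_cycle()] or bare 101-sample numeric.
#' @param reference The normative mean curve (101 samples, degrees); may be
#'   a row of a [build_normative_bank()] `curves` matrix.
#' @return GVS in degrees.
#' @export
gait_variable_score <- function(cycle, reference) {
  check_same_outcome(cycle, reference)
  d <- as_samples(cycle, "cycle") - as_samples(reference, "reference")
  sqrt(mean(d^2))
}

#' Gait Profile Score for one subject side
#'
#' The GPS is the root mean square of the nine gait variable scores — or,
#' equivalently here (all curves share the 101-point grid), the RMS over the
#' concatenated 9 x 101 pointwise deviations.
#'
#' @param curves Named list or 9 x 101 matrix (rows named by outcome) of one
#'   subject-side's cycle-mean curves for the nine GPS angles.
#' @param bank A [build_normative_bank()] result.
#' @return A list of class `gps_result`: `gvs` (named, degrees) and `gps`
#'   (degrees).
#' @export
gps_for_side <- function(curves, bank) {
  if (is.list(curves)) {
    curves <- do.call(rbind, curves[names(curves)])
  }
  need <- rownames(bank$curves)
  missing <- setdiff(need, rownames(curves))
  if (length(missing)) {
    abort_data(sprintf("GPS coverage error: missing outcome(s) %s",
                       paste(missing, collapse = ", ")))
  }
  gvs <- vapply(need, function(o)
    sqrt(mean((curves[o, ] - bank$curves[o, ])^2)), numeric(1))
  structure(list(gvs = gvs, gps = sqrt(mean(gvs^2))), class = "gps_result")
}

#' @export
print.gps_result <- function(x, ...) {
  cat(sprintf("<gps_result> GPS %.2f deg (GVS %.2f-%.2f deg)\n",
              x$gps, min(x$gvs), max(x$gvs)))
  invisible(x)
}

#' Per-subject Gait Profile Scores for one system
#'
#' Computes each subject's per-side GPS (on the subject-side cycle-mean
#' curves, session 1) against the system's normative bank, and the left/right
#' average.
#'
#' @param table A [cohort_table()].
#' @param bank A [build_normative_bank()] for the desired system.
#' @return A `data.table` with one row per subject: `subject_id`, `group`,
#'   `gps_left`, `gps_right`, `gps` (side mean, degrees).
#' @export
gps_table <- function(table, bank) {
  dt <- as.data.table(cohort_table(table))
  sys <- bank$system
  dt <- dt[session == 1L & system == sys & outcome %in% rownames(bank$curves)]
  if (!nrow(dt)) abort_data("no session-1 cycles for the bank's system")
  means <- dt[, c(.(count = .N), as.list(colMeans(.SD))),
              by = .(subject_id, group, side, outcome), .SDcols = SAMPLE_COLS]
  res <- means[, {
    m <- as.matrix(.SD[, SAMPLE_COLS, with = FALSE])
    rownames(m) <- outcome
    .(gps = gps_for_side(m, bank)$gps)
  }, by = .(subject_id, group, side)]
  wide <- dcast(res, subject_id + group ~ side, value.var = "gps")
  setnames(wide, c("left", "right"), c("gps_left", "gps_right"))
  wide[, gps := (gps_left + gps_right) / 2]
  setorderv(wide, "subject_id")
  wide[]
}

#' Flag a GPS difference against the group's minimal detectable change
#'
#' @param delta_gps GPS difference(s), degrees.
#' @param group `"AS"`, `"CP"` or `"OMD"` (recycled).
#' @param config An [analysis_config()] carrying the MDC thresholds.
#' @return Logical: `TRUE` iff `|delta_gps|` strictly exceeds the group MDC
#'   (boundary equality does not flag — the MDC is the smallest change
#'   beyond measurement error).
#' @export
mdc_flag <- function(delta_gps, group, config = analysis_config()) {
  if (!all(group %in% GROUPS)) {
    abort_validation(sprintf("unknown group(s): %s",
                             paste(setdiff(group, GROUPS), collapse = ", ")))
  }
  mdc <- ifelse(group == "AS", config$mdc_as, config$mdc_patho)
  abs(delta_gps) > mdc
}

#' Tukey-rule outliers of a GPS distribution
#'
#' @param gps_values Named numeric vector (names = subject ids) of per-subject
#'   side-mean GPS values; at least 4.
#' @return Character vector of flagged subject ids (values beyond 1.5 IQR
#'   from the quartiles).
#' @export
find_outliers <- function(gps_values) {
  if (length(gps_values) < 4L) {
    abort_validation("at least 4 subjects are required for outlier detection")
  }
  if (is.null(names(gps_values))) {
    names(gps_values) <- as.character(seq_along(gps_values))
  }
  q <- quantile(gps_values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  flag <- gps_values < q[1L] - 1.5 * iqr | gps_values > q[2L] + 1.5 * iqr
  names(gps_values)[flag]
}
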