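# Core domain vocabulary and the long-format cohort container.

#' Kinematic outcome identifiers
#'
#' The eleven most commonly reported lower-limb gait kinematic outcomes:
#' pelvis, hip and knee angles in the sagittal, frontal and transverse planes,
#' ankle dorsi/plantar flexion and the foot progression angle. All angle
#' curves handled by this package are time-normalized to 101 samples
#' (0--100\% of the gait cycle, inclusive) in degrees.
#'
#' @format Character vector of length 11.
#' @export
KINEMATIC_OUTCOMES <- c(
  "pelvis_tilt", "pelvis_obliquity", "pelvis_rotation",
  "hip_flexion", "hip_abduction", "hip_rotation",
  "knee_flexion", "knee_abduction", "knee_rotation",
  "ankle_flexion", "foot_progression"
)

#' Gait Profile Score outcome subset
#'
#' The nine angles entering the Gait Profile Score: pelvis and hip angles in
#' all three planes, knee and ankle angles in the sagittal plane, and the
#' foot progression angle (knee frontal/transverse angles are excluded).
#'
#' @format Character vector of length 9.
#' @export
GPS_OUTCOMES <- setdiff(KINEMATIC_OUTCOMES, c("knee_abduction", "knee_rotation"))

#' Anatomical plane of each kinematic outcome
#' @format Named character vector (sagittal/frontal/transverse).
#' @export
OUTCOME_PLANES <- c(
  pelvis_tilt = "sagittal", pelvis_obliquity = "frontal",
  pelvis_rotation = "transverse",
  hip_flexion = "sagittal", hip_abduction = "frontal",
  hip_rotation = "transverse",
  knee_flexion = "sagittal", knee_abduction = "frontal",
  knee_rotation = "transverse",
  ankle_flexion = "sagittal", foot_progression = "transverse"
)

# Segment/joint label used for reliability tables.
OUTCOME_JOINTS <- c(
  pelvis_tilt = "pelvis", pelvis_obliquity = "pelvis",
  pelvis_rotation = "pelvis",
  hip_flexion = "hip", hip_abduction = "hip", hip_rotation = "hip",
  knee_flexion = "knee", knee_abduction = "knee", knee_rotation = "knee",
  ankle_flexion = "ankle", foot_progression = "foot"
)

N_SAMPLES <- 101L
SAMPLE_COLS <- sprintf("s%03d", 0:100)
KEY_COLS <- c("subject_id", "group", "age_group", "session", "operator",
              "system", "side", "cycle_index", "outcome")
GROUPS <- c("AS", "CP", "OMD")
AGE_GROUPS <- c("child", "teen", "adult")
SYSTEMS <- c("OPTO", "IMU")
SIDES <- c("left", "right")

## ---- AngleCycle ------------------------------------------------------------

#' Construct an angle cycle
#'
#' One time-normalized joint-angle curve: 101 samples in degrees at
#' 0--100\% of the gait cycle, tagged with its outcome, side, cycle index
#' and measuring system.
#'
#' @param samples Numeric vector of exactly 101 finite angle values (degrees).
#' @param outcome One of [KINEMATIC_OUTCOMES].
#' @param side `"left"` or `"right"`.
#' @param cycle_index Non-negative integer.
#' @param system `"OPTO"` or `"IMU"`.
#' @return Numeric vector of class `"angle_cycle"` with metadata attributes.
#' @export
#' @examples
#' ac <- angle_cycle(sin(seq(0, 2 * pi, length.out = 101)) * 10, "knee_flexion")
angle_cycle <- function(samples, outcome, side = "left", cycle_index = 0L,
                        system = "OPTO") {
  samples <- as.numeric(samples)
  if (length(samples) != N_SAMPLES) {
    abort_validation(sprintf(
      "an angle cycle must have exactly %d samples, got %d",
      N_SAMPLES, length(samples)))
  }
  if (!all(is.finite(samples))) {
    abort_validation("angle cycle samples must all be finite")
  }
  outcome <- match.arg(outcome, KINEMATIC_OUTCOMES)
  side <- match.arg(side, SIDES)
  system <- match.arg(system, SYSTEMS)
  if (!is_scalar_number(cycle_index) || cycle_index < 0) {
    abort_validation("cycle_index must be a non-negative integer")
  }
  structure(samples,
            outcome = outcome, side = side,
            cycle_index = as.integer(cycle_index), system = system,
            class = "angle_cycle")
}

#' @export
print.angle_cycle <- function(x, ...) {
  cat(sprintf("<angle_cycle> %s %s cycle %d [%s]: %d samples, ROM %.1f deg\n",
              attr(x, "outcome"), attr(x, "side"), attr(x, "cycle_index"),
              attr(x, "system"), length(x), max(x) - min(x)))
  invisible(x)
}

# Coerce an angle_cycle or a bare length-101 numeric to plain samples.
as_samples <- function(x, what = "curve") {
  if (inherits(x, "angle_cycle")) return(as.numeric(unclass(x)))
  if (is.numeric(x) && length(x) == N_SAMPLES) return(as.numeric(x))
  abort_validation(sprintf("%s must be an angle_cycle or a numeric vector of %d samples",
                           what, N_SAMPLES))
}

# Error if two cycles carry conflicting outcome tags (bare numerics pass).
check_same_outcome <- function(a, b) {
  oa <- attr(a, "outcome"); ob <- attr(b, "outcome")
  if (!is.null(oa) && !is.null(ob) && !identical(oa, ob)) {
    abort_pairing(sprintf("cannot pair cycles of different outcomes: %s vs %s",
                          oa, ob))
  }
  invisible(NULL)
}

## ---- CohortTable -----------------------------------------------------------

#' Validate and class a long-format cohort table
#'
#' A cohort table holds one row per angle cycle, keyed by subject, group,
#' age group, session, operator, system, side, cycle index and outcome, with
#' 101 sample columns `s000` ... `s100` (degrees). Session 1 is always led
#' by operator A; session 2 may be led by operator A or B.
#'
#' @param x A data.frame with the key columns and the 101 sample columns.
#' @return A `data.table` of class `cohort_table` (keys coerced to canonical
#'   types, sample columns numeric).
#' @export
cohort_table <- function(x) {
  dt <- as.data.table(x)
  missing <- setdiff(c(KEY_COLS, SAMPLE_COLS), names(dt))
  if (length(missing)) {
    abort_format(sprintf("cohort table is missing column(s): %s",
                         paste(utils::head(missing, 5L), collapse = ", ")))
  }
  for (col in SAMPLE_COLS) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        abort_parse(sprintf("non-numeric sample value in column %s, row %d",
                            col, bad[1L]))
      }
      set(dt, j = col, value = vn)
    }
    if (anyNA(dt[[col]]) || any(!is.finite(dt[[col]]))) {
      abort_parse(sprintf("missing or non-finite sample value in column %s, row %d",
                          col, which(!is.finite(dt[[col]]))[1L]))
    }
  }
  set(dt, j = "subject_id", value = as.character(dt$subject_id))
  set(dt, j = "session", value = as.integer(dt$session))
  set(dt, j = "cycle_index", value = as.integer(dt$cycle_index))
  for (col in c("group", "age_group", "operator", "system", "side", "outcome")) {
    set(dt, j = col, value = as.character(dt[[col]]))
  }
  check_in <- function(col, allowed) {
    bad <- setdiff(unique(dt[[col]]), allowed)
    if (length(bad)) {
      abort_format(sprintf("invalid %s value(s): %s (allowed: %s)", col,
                           paste(bad, collapse = ", "),
                           paste(allowed, collapse = ", ")))
    }
  }
  check_in("group", GROUPS); check_in("age_group", AGE_GROUPS)
  check_in("system", SYSTEMS); check_in("side", SIDES)
  check_in("outcome", KINEMATIC_OUTCOMES)
  check_in("operator", c("A", "B"))
  if (nrow(dt)) {
    if (any(!dt$session %in% c(1L, 2L))) {
      abort_format("session must be 1 or 2")
    }
    if (any(dt$session == 1L & dt$operator != "A")) {
      abort_format("session 1 must be led by operator A")
    }
    if (any(dt$cycle_index < 0L)) abort_format("cycle_index must be >= 0")
    dup <- duplicated(dt, by = KEY_COLS)
    if (any(dup)) {
      d <- dt[which(dup)[1L], ..KEY_COLS]
      abort_integrity(sprintf(
        "duplicate cycle key: subject %s session %d operator %s system %s side %s cycle %d outcome %s",
        d$subject_id, d$session, d$operator, d$system, d$side, d$cycle_index,
        d$outcome))
    }
  }
  setcolorder(dt, c(KEY_COLS, SAMPLE_COLS))
  setattr(dt, "class", c("cohort_table", class(data.table())))
  dt[]
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d cycles | %d subjects | groups: %s | systems: %s\n",
    nrow(x), length(unique(x$subject_id)),
    paste(sort(unique(x$group)), collapse = "/"),
    paste(sort(unique(x$system)), collapse = "/")))
  invisible(x)
}

# Extract the sample matrix (n x 101) of a cohort table subset.
sample_matrix <- function(dt) as.matrix(dt[, SAMPLE_COLS, with = FALSE])

## ---- CSV I/O ---------------------------------------------------------------

#' Read a long-format gait-cycle table
#'
#' Reads a comma-separated UTF-8 file with one row per time-normalized angle
#' cycle (header: the nine key columns plus `s000`...`s100`) and validates it
#' into a [cohort_table()].
#'
#' @param path Path to a cycles CSV file.
#' @return A `cohort_table`.
#' @export
read_cycles_csv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cycles file not found: %s", path))
  dt <- fread(path, sep = ",", header = TRUE)
  tab <- cohort_table(dt)
  gv_log("io", sprintf("read %d cycles from %s", nrow(tab), path))
  tab
}

#' Write a long-format gait-cycle table
#'
#' Rows are sorted by all key fields before writing, so the output is a pure
#' function of the table content: writing the same table twice yields
#' byte-identical files.
#'
#' @param table A [cohort_table()] (or coercible data.frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(table, path) {
  tab <- cohort_table(table)
  setorderv(tab, KEY_COLS)
  ok <- tryCatch({
    fwrite(tab, path, sep = ",", quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write cycles file: %s", path))
  gv_log("io", sprintf("wrote %d cycles to %s", nrow(tab), path))
  invisible(path)
}
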