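# Gait-like waveform templates and the synthetic error structure.

# Periodic Gaussian bump centered at c (cycle fraction) with width w: the bump
# is wrapped at both cycle ends so sample 0 and sample 100 agree.
periodic_bump <- function(t, c, w) {
  exp(-0.5 * ((t - c) / w)^2) +
    exp(-0.5 * ((t - c - 1) / w)^2) +
    exp(-0.5 * ((t - c + 1) / w)^2)
}

# Fixed closed-form template shapes (degrees) on t in [0, 1]. Amplitudes are
# chosen to mimic typical adult gait curves: a double-bump knee flexion with
# 55-60 deg range, low-amplitude pelvic curves, an ankle plantarflexion dip
# at push-off, etc.
template_curve <- function(outcome, t) {
  switch(outcome,
    pelvis_tilt      = 12 + 1.0 * sin(4 * pi * t) + 0.5 * sin(2 * pi * t),
    pelvis_obliquity = 3.0 * sin(2 * pi * t) + 1.0 * sin(4 * pi * t),
    pelvis_rotation  = 5.0 * sin(2 * pi * t),
    hip_flexion      = 12 + 18 * cos(2 * pi * (t - 0.05)),
    hip_abduction    = 2 + 4 * cos(2 * pi * (t - 0.85)) + 1.5 * sin(4 * pi * t),
    hip_rotation     = -2 + 4 * sin(2 * pi * (t - 0.2)),
    knee_flexion     = 5 + 14 * periodic_bump(t, 0.15, 0.07) +
                           58 * periodic_bump(t, 0.73, 0.09),
    knee_abduction   = 1 + 2 * sin(2 * pi * t) + 1.5 * periodic_bump(t, 0.7, 0.1),
    knee_rotation    = 3 + 5 * sin(2 * pi * (t - 0.6)),
    ankle_flexion    = 10 * sin(2 * pi * (t - 0.4)) -
                           18 * periodic_bump(t, 0.62, 0.05),
    foot_progression = -8 + 4 * sin(2 * pi * t) + 2 * sin(4 * pi * t),
    abort_validation(sprintf("unknown outcome: %s", outcome))
  )
}

#' Build the per-outcome template bank
#'
#' Deterministic (given `seed`) bank of gait-like template curves, one per
#' kinematic outcome, on the 101-point gait-cycle grid. A small seeded smooth
#' perturbation (RMS 0.3 degrees) individualizes banks across seeds while
#' preserving the shape invariants: knee flexion range of motion within
#' 50--70 degrees, pelvic curves below 15 degrees of range, and periodicity
#' (first and last samples within 1 degree).
#'
#' @param seed Integer seed.
#' @return A list of class `template_bank` with elements `curves` (11 x 101
#'   matrix, rows named by outcome) and `rom` (named vector of template
#'   ranges of motion, degrees).
#' @export
make_template_bank <- function(seed = 1L) {
  with_seed(seed, {
    t <- seq(0, 1, length.out = N_SAMPLES)
    curves <- t(vapply(KINEMATIC_OUTCOMES, template_curve,
                       numeric(N_SAMPLES), t = t))
    curves <- curves + smooth_random_curves(length(KINEMATIC_OUTCOMES), 0.3)
    rownames(curves) <- KINEMATIC_OUTCOMES
    rom <- apply(curves, 1L, function(x) max(x) - min(x))
    bank <- structure(list(curves = curves, rom = rom, seed = as.integer(seed)),
                      class = "template_bank")
    validate_template_bank(bank)
    bank
  })
}

validate_template_bank <- function(bank) {
  curves <- bank$curves
  stopifnot(identical(rownames(curves), KINEMATIC_OUTCOMES),
            ncol(curves) == N_SAMPLES)
  if (bank$rom[["knee_flexion"]] < 50 || bank$rom[["knee_flexion"]] > 70) {
    abort_validation("template invariant violated: knee flexion ROM outside [50, 70] deg")
  }
  pelvis <- grep("^pelvis", KINEMATIC_OUTCOMES, value = TRUE)
  if (any(bank$rom[pelvis] >= 15)) {
    abort_validation("template invariant violated: pelvis template ROM must stay below 15 deg")
  }
  gap <- abs(curves[, 1L] - curves[, N_SAMPLES])
  if (any(gap >= 1)) {
    abort_validation("template invariant violated: curves must be periodic within 1 deg")
  }
  invisible(bank)
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %d outcomes, seed %d; ROM %.1f-%.1f deg\n",
              nrow(x$curves), x$seed, min(x$rom), max(x$rom)))
  invisible(x)
}

## ---- error model -----------------------------------------------------------

# Default per-outcome between-system offset means (degrees). The pelvic tilt
# offset is dominated by the neutral-pelvis definition mismatch between the
# inertial calibration and the marker model and defaults to 15 degrees; the
# remaining outcomes carry a moderate anatomical-frame offset.
default_offset_means <- function() {
  off <- setNames(rep(6, length(KINEMATIC_OUTCOMES)), KINEMATIC_OUTCOMES)
  off[["pelvis_tilt"]] <- 15
  off
}

#' Specify the between-system error model
#'
#' Describes how the synthetic IMU curves deviate from their matched
#' optoelectronic curves: a constant per-cycle angular offset (subject-level
#' mean plus per-condition sensor-placement draw plus per-cycle jitter) and
#' zero-mean waveform noise (a smooth correlated component that degrades the
#' between-system waveform correlation, plus white sample noise). The smooth
#' component is scaled per anatomical plane via `cc_degradation`, reflecting
#' the poorer transverse-plane agreement of inertial systems.
#'
#' @param offset_mean Named per-outcome offset means (degrees), or a single
#'   number recycled over outcomes. Default: 15 for pelvic tilt, 6 elsewhere.
#' @param offset_sd Between-subject SD of the constant offset (degrees).
#' @param placement_sd SD of the per-condition (session x operator) offset
#'   re-draw, emulating sensor re-placement (degrees).
#' @param cycle_jitter_sd SD of the per-cycle offset jitter (degrees).
#' @param noise_sd RMS of the smooth correlated waveform noise (degrees).
#' @param white_sd SD of additive white sample noise (degrees).
#' @param cc_degradation Named per-plane multiplier of `noise_sd`.
#' @param opto_noise_sd RMS of smooth measurement noise added to the
#'   optoelectronic curves themselves (default 0: the OPTO curve is the core
#'   curve and the IMU curve is OPTO plus offset plus noise). Setting it equal
#'   to `noise_sd` with all offsets at zero yields two exchangeable systems,
#'   the null world used for type-I-error checks.
#' @return A list of class `error_model`.
#' @export
error_model <- function(offset_mean = default_offset_means(),
                        offset_sd = 2.0,
                        placement_sd = 2.0,
                        cycle_jitter_sd = 0.5,
                        noise_sd = 2.0,
                        white_sd = 0.3,
                        cc_degradation = c(sagittal = 1, frontal = 1.2,
                                           transverse = 1.8),
                        opto_noise_sd = 0) {
  if (length(offset_mean) == 1L && is.null(names(offset_mean))) {
    offset_mean <- setNames(rep(as.numeric(offset_mean),
                                length(KINEMATIC_OUTCOMES)), KINEMATIC_OUTCOMES)
  }
  missing <- setdiff(KINEMATIC_OUTCOMES, names(offset_mean))
  if (length(missing)) {
    abort_validation(sprintf("offset_mean missing outcome(s): %s",
                             paste(missing, collapse = ", ")))
  }
  for (nm in c("offset_sd", "placement_sd", "cycle_jitter_sd", "noise_sd",
               "white_sd", "opto_noise_sd")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0) {
      abort_validation(sprintf("'%s' must be a non-negative number", nm))
    }
  }
  if (!all(c("sagittal", "frontal", "transverse") %in% names(cc_degradation)) ||
      any(cc_degradation < 0)) {
    abort_validation("'cc_degradation' needs non-negative sagittal/frontal/transverse entries")
  }
  structure(list(
    offset_mean = offset_mean[KINEMATIC_OUTCOMES],
    offset_sd = offset_sd, placement_sd = placement_sd,
    cycle_jitter_sd = cycle_jitter_sd,
    noise_sd = noise_sd, white_sd = white_sd,
    cc_degradation = cc_degradation,
    opto_noise_sd = opto_noise_sd
  ), class = "error_model")
}

#' A null (zero) error model: IMU cycles identical to OPTO cycles
#' @param noise_sd,opto_noise_sd Optional symmetric noise (see [error_model()]).
#' @return An `error_model` with all offsets zero.
#' @export
null_error_model <- function(noise_sd = 0, opto_noise_sd = noise_sd) {
  error_model(offset_mean = 0, offset_sd = 0, placement_sd = 0,
              cycle_jitter_sd = 0, noise_sd = noise_sd, white_sd = 0,
              cc_degradation = c(sagittal = 1, frontal = 1, transverse = 1),
              opto_noise_sd = opto_noise_sd)
}

## ---- variance specification ------------------------------------------------

#' Specify variance components for discrete-parameter generation
#'
#' Between-subject, between-session, between-operator, between-cycle and
#' residual (subject x condition) variances, in squared degrees, applied as
#' constant angular offsets when generating optoelectronic curves. Session
#' and operator are two-level classes; their effects are generated as exact
#' plus/minus contrasts whose sample variance equals the stated component, so
#' the class variance of a generated cohort is the stated value rather than a
#' one-degree-of-freedom random draw.
#'
#' @param subject,session,operator,cycle,residual Non-negative variances
#'   (degrees squared).
#' @return A list of class `variance_spec`.
#' @export
variance_spec <- function(subject = 9, session = 0.5, operator = 0.5,
                          cycle = 1.0, residual = 0.25) {
  comps <- c(subject = subject, session = session, operator = operator,
             cycle = cycle, residual = residual)
  if (any(!is.finite(comps)) || any(comps < 0)) {
    abort_validation("all variance components must be finite and >= 0")
  }
  structure(as.list(comps), class = "variance_spec")
}
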