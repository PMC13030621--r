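# Seeded synthetic paired-system gait cohorts.

# Subject-level deviation scale (RMS, degrees) of the smooth individual gait
# signature around the template, per outcome. Together with the constant
# between-subject offset (variance_spec$subject) these are calibrated so an
# asymptomatic cohort scores a Gait Profile Score near 5 degrees against its
# own group-mean bank.
DEV_SCALE <- c(
  pelvis_tilt = 2, pelvis_obliquity = 2, pelvis_rotation = 3,
  hip_flexion = 4, hip_abduction = 2.5, hip_rotation = 4.5,
  knee_flexion = 4.5, knee_abduction = 2.5, knee_rotation = 4,
  ankle_flexion = 3.5, foot_progression = 4.5
)

# Per-outcome RMS (degrees) of the fixed cerebral-palsy deviation field
# (crouch-like knee/hip flexion excess, equinus-like ankle offset, anterior
# pelvic tilt, internal rotation / in-toeing), scaled per subject by severity.
CP_PATHO_RMS <- c(
  pelvis_tilt = 5, pelvis_obliquity = 3, pelvis_rotation = 3,
  hip_flexion = 7, hip_abduction = 4, hip_rotation = 6,
  knee_flexion = 10, knee_abduction = 4, knee_rotation = 5,
  ankle_flexion = 8, foot_progression = 6
)

# Per-outcome RMS (degrees) of the heterogeneous per-subject random deviation
# mixture of the other-motor-disorders group.
OMD_PATHO_RMS <- c(
  pelvis_tilt = 4.8, pelvis_obliquity = 4.8, pelvis_rotation = 4.8,
  hip_flexion = 4.8, hip_abduction = 4.8, hip_rotation = 4.8,
  knee_flexion = 4.8, knee_abduction = 4, knee_rotation = 4,
  ankle_flexion = 4.8, foot_progression = 4.8
)

# Fixed crouch/equinus-flavoured deviation shapes for the CP group,
# normalized to unit RMS then scaled by CP_PATHO_RMS and subject severity.
cp_pattern_curve <- function(outcome, t) {
  raw <- switch(outcome,
    pelvis_tilt      = rep(1, length(t)),                       # anterior tilt
    pelvis_obliquity = 0.8 + 0.6 * sin(2 * pi * t),
    pelvis_rotation  = 0.7 + 0.7 * sin(2 * pi * (t - 0.1)),
    hip_flexion      = 1 + 0.4 * periodic_bump(t, 0.5, 0.2),    # crouch hip
    hip_abduction    = -0.8 - 0.5 * sin(2 * pi * t),
    hip_rotation     = 1 + 0.3 * sin(2 * pi * t),               # internal rot.
    knee_flexion     = 1 + 0.6 * periodic_bump(t, 0.35, 0.18),  # crouch knee
    knee_abduction   = 0.9 + 0.4 * sin(2 * pi * (t - 0.3)),
    knee_rotation    = 0.9 + 0.4 * sin(2 * pi * t),
    ankle_flexion    = -(1 + 0.4 * periodic_bump(t, 0.55, 0.15)), # equinus
    foot_progression = -(0.9 + 0.4 * sin(2 * pi * t))           # in-toeing
  )
  raw / sqrt(mean(raw^2))
}

# Age-group layout of the default cohort (children/teens/adults per group),
# recycled proportionally for non-default group sizes.
age_layout <- function(group, n) {
  counts <- switch(group,
    AS = c(child = 4, teen = 5, adult = 6),
    CP = c(child = 8, teen = 5, adult = 2),
    OMD = c(child = 13, teen = 3, adult = 9))
  base <- rep(names(counts), counts)
  rep_len(base, n)
}

#' Simulate a paired two-system gait cohort
#'
#' Generates a seeded synthetic cohort emulating a concurrent-validity study
#' design: three groups (asymptomatic AS, cerebral palsy CP, other motor
#' disorders OMD), each subject measured by an optoelectronic reference
#' (OPTO) and an inertial system (IMU) on both sides over several gait
#' cycles and all kinematic outcomes. Session 1 (operator A) covers every
#' subject; a reliability subset returns for session 2 led consecutively by
#' operators A and B.
#'
#' The optoelectronic curve of a cycle is the outcome template plus a smooth
#' subject gait signature, a group pathology deviation field scaled by a
#' per-subject severity, constant subject/session/operator/cycle offsets
#' drawn from `variance`, and smooth stride-to-stride waveform variability.
#' The matched IMU curve adds a constant angular offset (subject mean,
#' per-condition sensor-placement draw, per-cycle jitter) and waveform noise
#' as specified by `error`.
#'
#' @param n_as,n_cp,n_omd Group sizes (default 15/15/25).
#' @param cycles_per_subject Gait cycles per side and condition (default 5).
#' @param error An [error_model()].
#' @param variance A [variance_spec()].
#' @param seed Integer seed; identical seeds and parameters give bit-identical
#'   tables.
#' @param outcomes Outcomes to generate (default all 11).
#' @param reliability_n Named vector: how many subjects per group return for
#'   session 2 (default `c(AS = 13, CP = 7, OMD = 7)`, a 27-subject
#'   reliability subset). Set to `NULL` for a session-1-only
#'   cohort.
#' @param stride_waveform_rms RMS (degrees) of the smooth stride-to-stride
#'   waveform variability shared by both systems. Default 1.
#' @return A [cohort_table()].
#' @export
#' @examples
#' tab <- simulate_cohort(n_as = 2, n_cp = 2, n_omd = 2,
#'                        cycles_per_subject = 1, seed = 7,
#'                        reliability_n = NULL)
#' nrow(tab)  # 2 subjects/group * 2 systems * 2 sides * 11 outcomes
simulate_cohort <- function(n_as = 15L, n_cp = 15L, n_omd = 25L,
                            cycles_per_subject = 5L,
                            error = error_model(),
                            variance = variance_spec(),
                            seed = 1L,
                            outcomes = KINEMATIC_OUTCOMES,
                            reliability_n = c(AS = 13L, CP = 7L, OMD = 7L),
                            stride_waveform_rms = 1.0) {
  for (nm in c("n_as", "n_cp", "n_omd", "cycles_per_subject")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 1 || v != round(v)) {
      abort_validation(sprintf("'%s' must be a positive integer", nm))
    }
  }
  if (!inherits(error, "error_model")) {
    abort_validation("'error' must be an error_model()")
  }
  if (!inherits(variance, "variance_spec")) {
    abort_validation("'variance' must be a variance_spec()")
  }
  outcomes <- match.arg(outcomes, KINEMATIC_OUTCOMES, several.ok = TRUE)
  if (!is_scalar_number(stride_waveform_rms) || stride_waveform_rms < 0) {
    abort_validation("'stride_waveform_rms' must be >= 0")
  }

  bank <- make_template_bank(seed)
  body_seed <- as.integer((as.numeric(seed) + 1) %% .Machine$integer.max)

  with_seed(body_seed, {
    ## subjects ---------------------------------------------------------------
    groups_n <- c(AS = n_as, CP = n_cp, OMD = n_omd)
    subjects <- rbindlist(lapply(GROUPS, function(g) {
      n <- groups_n[[g]]
      data.table(subject_id = sprintf("%s%02d", g, seq_len(n)),
                 group = g, age_group = age_layout(g, n))
    }))
    S <- nrow(subjects)
    K <- length(outcomes)
    sev <- pmax(0.3, rnorm(S, mean = 1, sd = 0.25))
    subjects[, severity := fifelse(group == "AS", 0, sev)]

    rel <- rep(FALSE, S)
    if (!is.null(reliability_n)) {
      for (g in GROUPS) {
        k <- min(reliability_n[[g]] %||% 0L, groups_n[[g]])
        rel[which(subjects$group == g)[seq_len(k)]] <- TRUE
      }
    }
    subjects[, reliability := rel]

    ## measurement conditions --------------------------------------------------
    subjects[, subj_idx := .I]
    conds <- subjects[, {
      ses <- 1L; op <- "A"
      if (reliability) { ses <- c(1L, 2L, 2L); op <- c("A", "A", "B") }
      .(session = ses, operator = op)
    }, by = .(subj_idx, subject_id, group, age_group, severity)]
    conds[, cond_idx := .I]
    C <- nrow(conds)

    ## row grid (one row per future OPTO cycle) -------------------------------
    grid <- CJ(cond_idx = conds$cond_idx, side = SIDES, outcome = outcomes,
               cycle_index = 0:(cycles_per_subject - 1L), sorted = TRUE)
    grid <- conds[grid, on = "cond_idx"]
    R <- nrow(grid)
    o_idx <- match(grid$outcome, outcomes)
    side_idx <- match(grid$side, SIDES)
    dev_row <- (grid$subj_idx - 1L) * 2L + side_idx  # (subject, side) key

    ## random effects ----------------------------------------------------------
    subj_const <- matrix(rnorm(S * K, 0, sqrt(variance$subject)), S, K)
    dev <- lapply(seq_len(K), function(j)
      smooth_random_curves(S * 2L, DEV_SCALE[[outcomes[j]]]))

    t01 <- seq(0, 1, length.out = N_SAMPLES)
    cp_pattern <- t(vapply(outcomes, function(o)
      cp_pattern_curve(o, t01) * CP_PATHO_RMS[[o]], numeric(N_SAMPLES)))

    # OMD: per-(subject, side) smooth curve (80% of the energy) plus a
    # per-subject constant offset (60% RMS), both scaled by severity.
    omd_curves <- lapply(seq_len(K), function(j)
      smooth_random_curves(S * 2L, 0.8 * OMD_PATHO_RMS[[outcomes[j]]]))
    omd_const <- matrix(rnorm(S * K, 0, 1), S, K) *
      rep(0.6 * OMD_PATHO_RMS[outcomes], each = S)

    sess_a <- sqrt(variance$session / 2)
    op_a <- sqrt(variance$operator / 2)
    sess_eff <- c(`1` = -sess_a, `2` = +sess_a)
    oper_eff <- c(A = -op_a, B = +op_a)
    cond_resid <- matrix(rnorm(C * K, 0, sqrt(variance$residual)), C, K)
    cycle_off <- rnorm(R, 0, sqrt(variance$cycle))
    waveform <- smooth_random_curves(R, stride_waveform_rms)

    ## core curves (shared physical stride) ------------------------------------
    M <- bank$curves[grid$outcome, , drop = FALSE]
    const <- subj_const[cbind(grid$subj_idx, o_idx)] +
      sess_eff[as.character(grid$session)] +
      oper_eff[grid$operator] +
      cond_resid[cbind(grid$cond_idx, o_idx)] +
      cycle_off
    M <- M + const
    M <- M + waveform
    for (j in seq_len(K)) {
      rows <- which(o_idx == j)
      M[rows, ] <- M[rows, ] + dev[[j]][dev_row[rows], , drop = FALSE]
      cp_rows <- rows[grid$group[rows] == "CP"]
      if (length(cp_rows)) {
        M[cp_rows, ] <- M[cp_rows, ] +
          outer(grid$severity[cp_rows], cp_pattern[j, ])
      }
      omd_rows <- rows[grid$group[rows] == "OMD"]
      if (length(omd_rows)) {
        M[omd_rows, ] <- M[omd_rows, ] +
          grid$severity[omd_rows] *
            (omd_curves[[j]][dev_row[omd_rows], , drop = FALSE] +
               omd_const[cbind(grid$subj_idx[omd_rows], j)])
      }
    }

    ## system-specific parts ---------------------------------------------------
    O <- M
    if (error$opto_noise_sd > 0) {
      O <- O + smooth_random_curves(R, error$opto_noise_sd)
    }

    imu_subj_off <- matrix(rnorm(S * K, 0, error$offset_sd), S, K) +
      rep(error$offset_mean[outcomes], each = S)
    imu_placement <- matrix(rnorm(C * K, 0, error$placement_sd), C, K)
    imu_jitter <- rnorm(R, 0, error$cycle_jitter_sd)
    I <- M +
      imu_subj_off[cbind(grid$subj_idx, o_idx)] +
      imu_placement[cbind(grid$cond_idx, o_idx)] +
      imu_jitter
    if (error$noise_sd > 0) {
      for (j in seq_len(K)) {
        rows <- which(o_idx == j)
        rms <- error$noise_sd *
          error$cc_degradation[[OUTCOME_PLANES[[outcomes[j]]]]]
        if (rms > 0) {
          I[rows, ] <- I[rows, ] + smooth_random_curves(length(rows), rms)
        }
      }
    }
    if (error$white_sd > 0) {
      I <- I + matrix(rnorm(R * N_SAMPLES, 0, error$white_sd), R, N_SAMPLES)
    }

    ## assemble ----------------------------------------------------------------
    keys <- grid[, .(subject_id, group, age_group, session, operator, side,
                     cycle_index, outcome)]
    make_half <- function(sys_name, mat) {
      dt <- copy(keys)
      dt[, system := sys_name]
      cbind(dt, as.data.table(`colnames<-`(mat, SAMPLE_COLS)))
    }
    tab <- cohort_table(rbind(make_half("OPTO", O), make_half("IMU", I)))
    setattr(tab, "gv_truth", list(
      bank = bank, subjects = as.data.frame(subjects),
      error = error, variance = variance, seed = as.integer(seed)))
    gv_log("simulate", sprintf("cohort: %d subjects, %d cycle rows", S, nrow(tab)))
    tab
  })
}

#' Simulate a subject-by-condition measurement table
#'
#' Direct generator for reliability parameter-recovery checks: one value per
#' subject and condition from the additive model
#' `value = subject effect + class effect + residual`. Subject effects and
#' residuals are Gaussian draws; the k class (condition) effects are exact
#' contrasts whose sample variance equals `sigma2_class`, matching the
#' fixed-class two-way model used by [fit_icc()].
#'
#' @param n_subjects Number of subjects.
#' @param sigma2_subject,sigma2_class,sigma2_residual Variance components
#'   (squared degrees), all `>= 0`.
#' @param k Number of conditions (default 2).
#' @param seed Integer seed.
#' @return A `data.table` with columns `subject`, `condition`, `value` and an
#'   attribute `gv_truth` holding the generating components and the analytic
#'   intraclass correlation.
#' @export
simulate_measurement_table <- function(n_subjects, sigma2_subject,
                                       sigma2_class, sigma2_residual,
                                       k = 2L, seed = 1L) {
  if (!is_scalar_number(n_subjects) || n_subjects < 2) {
    abort_validation("'n_subjects' must be >= 2")
  }
  comps <- c(sigma2_subject, sigma2_class, sigma2_residual)
  if (any(!is.finite(comps)) || any(comps < 0)) {
    abort_validation("variance components must be finite and >= 0")
  }
  with_seed(seed, {
    x <- seq_len(k)
    class_eff <- if (sigma2_class > 0) {
      sqrt(sigma2_class) * (x - mean(x)) / sd(x)
    } else rep(0, k)
    subj_eff <- rnorm(n_subjects, 0, sqrt(sigma2_subject))
    dt <- CJ(subject = seq_len(n_subjects), condition = seq_len(k))
    dt[, value := subj_eff[subject] + class_eff[condition] +
         rnorm(.N, 0, sqrt(sigma2_residual))]
    icc_true <- sigma2_subject /
      (sigma2_subject + sigma2_class + sigma2_residual)
    setattr(dt, "gv_truth", list(
      subject = sigma2_subject, class = sigma2_class,
      residual = sigma2_residual, icc = icc_true))
    dt[]
  })
}
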