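# Synthetic raw recordings: straight-line walks with marker trajectories,
# foot-mounted gyroscope streams, joint-angle streams and ground-truth gait
# events, plus wand-drop synchronization trials.

#' Simulate a straight-line instrumented walk
#'
#' Builds a raw paired recording of one walking pass with known ground truth:
#' \itemize{
#' \item marker trajectories (sacrum, heels, toes; meters at 100 Hz on the
#'   optoelectronic clock) whose anteroposterior heel/toe excursions relative
#'   to the sacrum peak exactly at the ground-truth foot strikes / foot offs;
#' \item per-foot inertial streams (sagittal angular velocity in deg/s and
#'   3-axis acceleration in g at 256 Hz) with one dominant positive mid-swing
#'   peak per stride and negative troughs centered at the ground-truth
#'   events, timestamped on an IMU clock shifted by `clock_offset` (and
#'   optionally drifting);
#' \item joint-angle streams for both systems (the IMU angles carry the
#'   default constant offsets), enabling end-to-end segmentation tests.
#' }
#'
#' @param n_strides Strides per side (>= 2).
#' @param cadence Strides per minute (default 55, a spontaneous adult pace).
#' @param clock_offset IMU clock minus marker clock at marker time 0, seconds.
#' @param seed Integer seed.
#' @param drift IMU clock drift (seconds gained per marker-clock second).
#' @param stride_length Meters per stride (default 1.2).
#' @param marker_noise_sd Marker position noise SD, meters (default 1e-3).
#' @param gyro_noise_sd Gyroscope noise SD, deg/s (default 5).
#' @param include_angles Generate the joint-angle streams (default TRUE).
#' @return A list of class `synthetic_walk`: `markers` (data.table),
#'   `imu` (per-side data.tables), `angles` (per system and side), and
#'   `truth` (ground-truth event times on both clocks, clock offset, drift,
#'   stride time).
#' @export
simulate_walk <- function(n_strides = 10L, cadence = 55, clock_offset = 0,
                          seed = 1L, drift = 0, stride_length = 1.2,
                          marker_noise_sd = 1e-3, gyro_noise_sd = 5,
                          include_angles = TRUE) {
  if (!is_scalar_number(n_strides) || n_strides < 2) {
    abort_validation("'n_strides' must be >= 2")
  }
  if (!is_scalar_number(cadence) || cadence <= 0) {
    abort_validation("'cadence' must be > 0 strides/min")
  }
  with_seed(seed, {
    T_str <- 60 / cadence
    rate_m <- 100; rate_i <- 256
    t0 <- 0.75 * T_str
    dur <- t0 + n_strides * T_str
    # periodic event families; the ground-truth lists keep only events far
    # enough from the recording edges to be detectable by BOTH detectors
    # (a strike needs its preceding mid-swing inside the recording, a foot
    # off its following mid-swing). Extrema closer to the edges may still be
    # picked up by a detector; cycle pairing aligns strikes by time.
    phase <- c(right = t0, left = t0 + T_str / 2)
    kk <- (-1):(n_strides + 1L)
    in_win <- function(x, lo, hi) x[x >= lo & x <= hi]
    fs_fam <- lapply(phase, function(p) p + kk * T_str)
    fo_fam <- lapply(fs_fam, function(x) x + 0.6 * T_str)
    ms_fam <- lapply(fs_fam, function(x) x - 0.2 * T_str)
    fs <- lapply(fs_fam, in_win, lo = 0.3 * T_str, hi = dur - 0.2 * T_str)
    fo <- lapply(fo_fam, in_win, lo = 0.2 * T_str, hi = dur - 0.3 * T_str)
    lobe_win <- function(x) in_win(x, 0.1 * T_str, dur - 0.1 * T_str)

    tm <- seq(0, dur, by = 1 / rate_m)
    v <- stride_length / T_str
    nz <- function(n) rnorm(n, 0, marker_noise_sd)
    sacrum_ap <- v * tm + nz(length(tm))
    mk <- data.table(time = tm, sacrum_ap = sacrum_ap,
                     sacrum_z = 1.0 + 0.01 * sin(2 * pi * tm / T_str))
    for (s in SIDES) {
      heel <- v * tm + 0.25 * cos(2 * pi * (tm - phase[[s]]) / T_str) +
        nz(length(tm))
      toe <- v * tm - 0.20 * cos(2 * pi * (tm - phase[[s]] - 0.6 * T_str) / T_str) +
        nz(length(tm))
      heel_z <- 0.03 * (1 - cos(2 * pi * (tm - phase[[s]]) / T_str)) / 2
      mk[, (paste0("heel_ap_", s)) := heel]
      mk[, (paste0("toe_ap_", s)) := toe]
      mk[, (paste0("heel_z_", s)) := heel_z]
    }

    gauss <- function(t, c, w) exp(-0.5 * ((t - c) / w)^2)
    tt <- seq(0, dur, by = 1 / rate_i)     # true time of the IMU samples
    t_imu <- tt + clock_offset + drift * tt  # stamped IMU clock
    imu <- list()
    for (s in SIDES) {
      w <- numeric(length(tt))
      for (c in lobe_win(ms_fam[[s]])) w <- w + 400 * gauss(tt, c, 0.065 * T_str)
      for (c in lobe_win(fs_fam[[s]])) w <- w - 120 * gauss(tt, c, 0.035)
      for (c in lobe_win(fo_fam[[s]])) w <- w - 100 * gauss(tt, c, 0.035)
      w <- w + rnorm(length(tt), 0, gyro_noise_sd)
      az <- 1 + rnorm(length(tt), 0, 0.05)
      for (c in lobe_win(fs_fam[[s]])) az <- az + 2 * gauss(tt, c, 0.01)
      imu[[s]] <- data.table(time = t_imu, gyro_sag = pmin(pmax(w, -2000), 2000),
                             ax = rnorm(length(tt), 0, 0.05),
                             ay = rnorm(length(tt), 0, 0.05),
                             az = pmin(pmax(az, -16), 16))
    }

    angles <- NULL
    if (include_angles) {
      offs <- default_offset_means()
      mk_ang <- function(time_base, side, offset_by_outcome, noise_sd) {
        ph <- ((time_base - phase[[side]]) / T_str) %% 1
        dt <- data.table(time = time_base)
        for (o in KINEMATIC_OUTCOMES) {
          dt[, (o) := template_curve(o, ph) + offset_by_outcome[[o]] +
               rnorm(length(time_base), 0, noise_sd)]
        }
        dt
      }
      zero_off <- setNames(rep(0, length(KINEMATIC_OUTCOMES)), KINEMATIC_OUTCOMES)
      angles <- list(
        OPTO = list(left = mk_ang(tm, "left", zero_off, 0.2),
                    right = mk_ang(tm, "right", zero_off, 0.2)),
        IMU = list(left = {
          a <- mk_ang(tt, "left", offs, 0.4); a[, time := t_imu]; a
        }, right = {
          a <- mk_ang(tt, "right", offs, 0.4); a[, time := t_imu]; a
        })
      )
    }

    to_imu_clock <- function(x) x + clock_offset + drift * x
    truth <- list(
      strikes = fs, offs = fo,
      strikes_imu = lapply(fs, to_imu_clock),
      offs_imu = lapply(fo, to_imu_clock),
      clock_offset = clock_offset, drift = drift,
      stride_time = T_str, duration = dur,
      marker_rate = rate_m, imu_rate = rate_i)
    structure(list(markers = mk, imu = imu, angles = angles, truth = truth),
              class = "synthetic_walk")
  })
}

#' @export
print.synthetic_walk <- function(x, ...) {
  cat(sprintf("<synthetic_walk> %d strides/side, %.2f s, clock offset %+.3f s\n",
              length(x$truth$strikes$right), x$truth$duration,
              x$truth$clock_offset))
  invisible(x)
}

#' Simulate a wand-drop synchronization trial
#'
#' A rigid wand carrying an IMU and a reflective marker is held still, then
#' dropped; the floor impact produces a distinct acceleration peak in the
#' inertial stream and the end of the descending phase in the marker's
#' vertical trajectory, at the same true instant.
#'
#' @param impact_time True impact time, seconds into the trial (marker clock).
#' @param seed Integer seed.
#' @param duration Trial length, seconds (default 5).
#' @param clock_offset IMU clock minus marker clock, seconds (default 0).
#' @param start_time Session time at which the trial starts, seconds
#'   (default 0); both streams carry absolute session timestamps, so two
#'   trials recorded at the session start and end identify a clock drift.
#' @param drift IMU clock drift, seconds gained per marker-clock second.
#' @param drop_height Wand release height, meters (default 0.8).
#' @param accel_noise_sd Accelerometer noise SD, g (default 0.02).
#' @param marker_noise_sd Marker noise SD, meters (default 5e-4).
#' @return A list of class `sync_trial`: `accel` (time, ax, ay, az at
#'   256 Hz, IMU clock), `marker` (time, z at 100 Hz, marker clock) and
#'   `truth` (impact times on both clocks).
#' @export
simulate_sync_trial <- function(impact_time = 2.5, seed = 1L, duration = 5,
                                clock_offset = 0, start_time = 0, drift = 0,
                                drop_height = 0.8,
                                accel_noise_sd = 0.02, marker_noise_sd = 5e-4) {
  t_fall <- sqrt(2 * drop_height / 9.81)
  if (!is_scalar_number(impact_time) ||
      impact_time <= t_fall + 0.1 || impact_time >= duration - 0.2) {
    abort_validation(sprintf(
      "'impact_time' must lie in (%.2f, %.2f) s for this trial", t_fall + 0.1,
      duration - 0.2))
  }
  with_seed(seed, {
    t_start <- impact_time - t_fall
    ti <- seq(0, duration, by = 1 / 256)
    az <- ifelse(ti < t_start, 1, ifelse(ti < impact_time, 0, 1))
    az <- az + 9 * exp(-0.5 * ((ti - impact_time) / 0.004)^2)
    to_imu <- function(x) (x + start_time) * (1 + drift) + clock_offset
    accel <- data.table(
      time = to_imu(ti),
      ax = rnorm(length(ti), 0, accel_noise_sd),
      ay = rnorm(length(ti), 0, accel_noise_sd),
      az = pmin(pmax(az + rnorm(length(ti), 0, accel_noise_sd), -16), 16))
    tmk <- seq(0, duration, by = 1 / 100)
    # the wand marker reaches the floor (z = 0) exactly at the impact: the
    # descent is continuous, so the peak downward speed sits at the contact
    z <- ifelse(tmk < t_start, drop_height,
                ifelse(tmk < impact_time,
                       drop_height - 0.5 * 9.81 * (tmk - t_start)^2, 0))
    marker <- data.table(time = tmk + start_time,
                         z = pmax(z, 0) + rnorm(length(tmk), 0, marker_noise_sd))
    structure(list(accel = accel, marker = marker,
                   truth = list(impact_time = impact_time + start_time,
                                impact_time_imu = to_imu(impact_time),
                                clock_offset = clock_offset, drift = drift)),
              class = "sync_trial")
  })
}
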