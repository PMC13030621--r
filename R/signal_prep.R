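# Signal preparation: clock synchronization from wand-drop impacts, gait
# event detection from marker coordinates (Zeni-style) and from raw foot
# angular velocity (single-channel gyroscope variant), cycle segmentation.

# Quadratic sub-sample refinement of an extremum at index i.
refine_extremum <- function(x, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(0)
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (abs(denom) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (x[i - 1L] - x[i + 1L]) / denom))
}

rate_from_time <- function(time) {
  dt <- median(diff(time))
  if (!is.finite(dt) || dt <= 0) abort_validation("time stamps must increase")
  1 / dt
}

## ---- synchronization -------------------------------------------------------

#' Detect the wand-drop impact time in an accelerometer stream
#'
#' The impact is the global maximum of the gravity-removed acceleration
#' magnitude |  ||a|| - 1 g | after light smoothing; it must exceed
#' `threshold` (g) to count as an impact.
#'
#' @param accel A data.frame with columns `time` (s) and `ax`, `ay`, `az` (g).
#' @param threshold Minimum deviation from 1 g, in g (default 4).
#' @return Impact time in seconds, on the stream's own clock.
#' @export
detect_impact_time <- function(accel, threshold = 4) {
  need <- c("time", "ax", "ay", "az")
  if (!is.data.frame(accel) || !all(need %in% names(accel))) {
    abort_validation("'accel' must have columns time, ax, ay, az")
  }
  rate <- rate_from_time(accel$time)
  if (nrow(accel) < 0.5 * rate) abort_validation("acceleration stream shorter than 0.5 s")
  dev <- abs(sqrt(accel$ax^2 + accel$ay^2 + accel$az^2) - 1)
  # 3-sample running mean: wide enough to kill single-sample glitches,
  # narrow enough not to smear a few-ms impact spike below threshold
  sm <- as.numeric(stats::filter(dev, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- dev[is.na(sm)]
  if (max(sm) < threshold) {
    abort_signal(sprintf("no impact found: peak %.2f g below threshold %.2f g",
                         max(sm), threshold))
  }
  i <- which.max(sm)
  accel$time[i] + refine_extremum(sm, i) / rate
}

#' Detect the floor-contact instant in a dropped marker's vertical trajectory
#'
#' Returns the time at which the downward velocity magnitude peaks,
#' immediately before the trajectory's height minimum (the free fall ends at
#' floor contact, where speed is maximal).
#'
#' @param marker_z A data.frame with columns `time` (s) and `z` (m).
#' @param min_drop Minimum height range to accept as a drop, m (default 0.1).
#' @return Contact time in seconds.
#' @export
detect_drop_event <- function(marker_z, min_drop = 0.1) {
  if (!is.data.frame(marker_z) || !all(c("time", "z") %in% names(marker_z))) {
    abort_validation("'marker_z' must have columns time, z")
  }
  z <- marker_z$z; time <- marker_z$time
  n <- length(z)
  rate <- rate_from_time(time)
  if (diff(range(z)) < min_drop) {
    abort_signal("no drop found: vertical range below threshold")
  }
  # velocity from raw backward differences: any smoothing smears the sharp
  # fall-to-rest transition and biases the contact time early, while marker
  # noise (sub-mm) is negligible against the multi-m/s fall speed
  i_floor <- which(z <= min(z) + 0.25 * min_drop)[1L]
  if (is.na(i_floor) || i_floor > n - 3L || i_floor < 3L) {
    abort_signal("no drop found: no stationary phase after the descent")
  }
  v <- c(0, diff(z)) * rate
  i <- which.max(-v[seq_len(min(n, i_floor + 2L))])
  # sub-sample refinement: the descent crosses the near-floor level once,
  # just before peak speed; interpolating that crossing and extrapolating
  # the residual fall beats quadratic refinement of the kinked velocity
  rest <- median(z[i_floor:n])
  thr <- rest + 0.01
  cross <- which(z <= thr)[1L]
  if (!is.na(cross) && cross > 1L && z[cross - 1L] > thr) {
    speed <- (z[cross - 1L] - z[cross]) * rate
    frac <- (z[cross - 1L] - thr) / (z[cross - 1L] - z[cross])
    time[cross - 1L] + frac / rate + (thr - rest) / max(speed, 1e-6)
  } else {
    time[i] + refine_extremum(-v, i) / rate
  }
}

#' Estimate the temporal offset (and drift) between the IMU and marker clocks
#'
#' Given matched impact times from one or two synchronization trials, fits
#' the between-clock relation. With one pair, `offset` is the plain time
#' difference and `drift` is undefined (`NA`). With two (or more) pairs, the
#' per-event differences `d = imu - marker` are fit as a line over IMU time:
#' `offset` is the difference extrapolated to IMU time 0, and `drift` is the
#' rate of the marker clock relative to the IMU clock minus one (seconds of
#' marker time gained per IMU second); IMU times map to the marker clock as
#' `marker = imu * (1 + drift) - offset`.
#'
#' @param sync_events_imu Impact times on the IMU clock (length 1 or 2).
#' @param sync_events_marker Matched impact times on the marker clock.
#' @return A list of class `sync_result`: `offset` (s), `drift` (s/s or NA),
#'   `residual` (RMS fit residual, s).
#' @export
synchronize <- function(sync_events_imu, sync_events_marker) {
  imu <- as.numeric(sync_events_imu); mk <- as.numeric(sync_events_marker)
  if (length(imu) != length(mk)) {
    abort_pairing(sprintf("mismatched sync event counts: %d IMU vs %d marker",
                          length(imu), length(mk)))
  }
  if (length(imu) < 1L) abort_pairing("at least one sync event pair is required")
  d <- imu - mk
  if (length(imu) == 1L) {
    res <- list(offset = d, drift = NA_real_, residual = 0)
  } else if (diff(range(imu)) < 1) {
    # events too close in time to identify a drift: replicate measurements
    res <- list(offset = mean(d), drift = NA_real_,
                residual = sqrt(mean((d - mean(d))^2)))
  } else {
    X <- cbind(1, imu)
    beta <- qr.solve(X, d)
    resid <- d - X %*% beta
    res <- list(offset = unname(beta[1L]), drift = unname(-beta[2L]),
                residual = sqrt(mean(resid^2)))
  }
  structure(res, class = "sync_result")
}

#' Map IMU-clock times onto the marker clock
#' @param times Times on the IMU clock (s).
#' @param sync A [synchronize()] result.
#' @return Times on the marker clock.
#' @export
imu_to_marker_time <- function(times, sync) {
  drift <- if (is.na(sync$drift)) 0 else sync$drift
  times * (1 + drift) - sync$offset
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> offset %+.4f s, drift %s, residual %.4g s\n",
              x$offset,
              if (is.na(x$drift)) "n/a" else sprintf("%+.2e s/s", x$drift),
              x$residual))
  invisible(x)
}

## ---- event detection -------------------------------------------------------

#' Bundle per-side gait events
#'
#' @param left,right Per-side lists with numeric `strikes` and `offs` (s).
#' @param source `"marker"` or `"imu"`.
#' @return A list of class `event_set`.
#' @export
event_set <- function(left, right, source = c("marker", "imu")) {
  source <- match.arg(source)
  for (s in list(left, right)) {
    for (f in c("strikes", "offs")) {
      v <- s[[f]]
      if (!is.numeric(v) || is.unsorted(v, strictly = TRUE)) {
        abort_validation(sprintf("event %s must be strictly increasing", f))
      }
    }
  }
  structure(list(left = left[c("strikes", "offs")],
                 right = right[c("strikes", "offs")], source = source),
            class = "event_set")
}

#' Coordinate-based gait event detection from marker trajectories
#'
#' Foot strikes are the local maxima of the heel-to-sacrum anteroposterior
#' distance along the walking direction and foot offs the local minima of
#' the toe-to-sacrum distance. The walking direction is estimated from the
#' sacrum displacement per pass, so back-and-forth walkway passes are both
#' processed; reversing the walking direction leaves the events unchanged.
#'
#' @param heel_ap,toe_ap,sacrum_ap Co-sampled anteroposterior positions (m)
#'   of one side's heel and toe markers and the sacrum marker.
#' @param rate Sampling rate, Hz.
#' @param t0 Time of the first sample, seconds (default 0).
#' @return A list with `strikes` and `offs` (seconds, sub-sample refined).
#' @export
detect_events_zeni <- function(heel_ap, toe_ap, sacrum_ap, rate, t0 = 0) {
  n <- length(sacrum_ap)
  if (length(heel_ap) != n || length(toe_ap) != n) {
    abort_validation("heel, toe and sacrum trajectories must be co-sampled")
  }
  ba <- butter2_lowpass(10, rate)
  heel <- filtfilt2(ba, heel_ap); toe <- filtfilt2(ba, toe_ap)
  sac <- filtfilt2(ba, sacrum_ap)
  if (diff(range(sac)) < 0.5) {
    abort_signal("no progression: sacrum displacement below 0.5 m")
  }
  v <- c(0, diff(sac)) * rate
  moving <- abs(v) > 0.1
  dir <- sign(v)
  # contiguous same-direction moving runs of at least 0.5 s form passes
  runs <- rle(dir * moving)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0 & runs$lengths >= 0.5 * rate
  strikes <- numeric(0); offs <- numeric(0)
  for (p in which(keep)) {
    idx <- starts[p]:ends[p]
    s <- runs$values[p]
    rel_h <- s * (heel[idx] - sac[idx])
    rel_t <- s * (toe[idx] - sac[idx])
    pk <- find_peaks(rel_h, min_height = mean(rel_h),
                     min_distance = round(0.5 * rate))
    tr <- find_troughs(rel_t, max_height = mean(rel_t),
                       min_distance = round(0.5 * rate))
    strikes <- c(strikes, vapply(pk, function(i)
      t0 + (idx[1L] + i - 2L + refine_extremum(rel_h, i)) / rate, 0))
    offs <- c(offs, vapply(tr, function(i)
      t0 + (idx[1L] + i - 2L + refine_extremum(-rel_t, i)) / rate, 0))
  }
  if (!length(strikes)) abort_signal("no progression: no gait events found")
  list(strikes = sort(strikes), offs = sort(offs))
}

#' Gyroscope-based gait event detection from foot angular velocity
#'
#' Single-channel variant of foot-worn inertial event detection: mid-swing
#' is detected as the dominant positive peaks of the sagittal angular
#' velocity; the foot strike is the first local minimum after a mid-swing
#' peak below an adaptive negative threshold, and the foot off the last such
#' minimum before the peak. All thresholds are relative (40% of the median
#' candidate peak height), so the detected times are invariant under
#' amplitude scaling of the signal. Returned times stay on the stream's own
#' (IMU) clock.
#'
#' @param gyro A data.frame with columns `time` (s) and `gyro_sag` (deg/s),
#'   or a numeric vector with `rate` (Hz) and `t0` given.
#' @param rate Sampling rate, Hz (ignored when `gyro` is a data.frame).
#' @param t0 Time of the first sample (vector input only).
#' @return A list with `strikes` and `offs` (seconds).
#' @export
detect_events_imu <- function(gyro, rate = NULL, t0 = 0) {
  if (is.data.frame(gyro)) {
    if (!all(c("time", "gyro_sag") %in% names(gyro))) {
      abort_validation("'gyro' must have columns time and gyro_sag")
    }
    time <- gyro$time; w <- gyro$gyro_sag
    rate <- rate_from_time(time)
  } else {
    if (is.null(rate)) abort_validation("'rate' is required for vector input")
    w <- as.numeric(gyro)
    time <- t0 + (seq_along(w) - 1L) / rate
  }
  if (length(w) < rate) abort_signal("insufficient strides: stream too short")
  ws <- filtfilt2(butter2_lowpass(17, rate), w)
  gmax <- max(ws)
  span <- diff(range(ws))
  if (gmax <= 0 || span < 1e-9) {
    abort_signal("insufficient strides: no positive angular-velocity peaks")
  }
  cand <- find_peaks(ws, min_height = 0.2 * gmax,
                     min_distance = round(0.25 * rate))
  if (length(cand) < 2L) {
    abort_signal("insufficient strides: fewer than 2 mid-swing peaks")
  }
  thr <- 0.4 * median(ws[cand])
  mids <- cand[ws[cand] > thr]
  if (length(mids) < 2L) {
    abort_signal("insufficient strides: fewer than 2 mid-swing peaks")
  }
  stride <- median(diff(mids))
  neg_thr <- -0.1 * thr
  strikes <- numeric(0); offs <- numeric(0)
  half <- round(0.5 * stride)
  n <- length(ws)
  for (m in mids) {
    lo <- max(1L, m - half); hi <- min(n, m + half)
    post <- find_troughs(ws[m:hi], max_height = neg_thr)
    if (length(post)) {
      i <- m + post[1L] - 1L
      strikes <- c(strikes, time[i] + refine_extremum(-ws, i) / rate)
    }
    pre <- find_troughs(ws[lo:m], max_height = neg_thr)
    if (length(pre)) {
      i <- lo + pre[length(pre)] - 1L
      offs <- c(offs, time[i] + refine_extremum(-ws, i) / rate)
    }
  }
  list(strikes = sort(unique(strikes)), offs = sort(unique(offs)))
}

# Greedy one-to-one matching of two sorted event-time lists within `tol`
# seconds; returns a 2-column index matrix (rows = matched pairs).
match_event_times <- function(a, b, tol) {
  used <- logical(length(b))
  out <- matrix(integer(0), ncol = 2L)
  for (i in seq_along(a)) {
    d <- abs(b - a[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      used[j] <- TRUE
      out <- rbind(out, c(i, j))
    }
  }
  out
}

## ---- cycle segmentation ----------------------------------------------------

#' Cut an angle time series into time-normalized gait cycles
#'
#' One cycle per consecutive pair of same-side foot strikes, linearly
#' resampled to the 101-point grid. Cycles whose duration deviates by more
#' than 40\% from the median cycle duration are discarded (automated
#' stand-in for manual event checking) and logged.
#'
#' @param angle_series A data.frame with columns `time` (s) and `value`
#'   (degrees), on the same clock as the events.
#' @param events Either a per-side list with element `strikes`, or an
#'   [event_set()] (then `side` selects the side).
#' @param side `"left"` or `"right"`.
#' @param outcome Outcome id to stamp on the cycles.
#' @param system `"OPTO"` or `"IMU"`.
#' @return A list of [angle_cycle()] objects, numbered consecutively from 0.
#' @export
segment_cycles <- function(angle_series, events, side = "left",
                           outcome = "knee_flexion", system = "OPTO") {
  if (!is.data.frame(angle_series) ||
      !all(c("time", "value") %in% names(angle_series))) {
    abort_validation("'angle_series' must have columns time and value")
  }
  strikes <- if (inherits(events, "event_set")) {
    events[[match.arg(side, SIDES)]]$strikes
  } else {
    events$strikes
  }
  if (length(strikes) < 2L) {
    abort_signal("no complete cycle: fewer than 2 foot strikes")
  }
  durs <- diff(strikes)
  med <- median(durs)
  keep <- abs(durs - med) <= 0.4 * med
  if (any(!keep)) {
    gv_log("segment", sprintf("discarded %d cycle(s) failing the 40%% duration rule",
                              sum(!keep)))
  }
  cycles <- list()
  ci <- 0L
  for (k in which(keep)) {
    grid <- seq(strikes[k], strikes[k + 1L], length.out = N_SAMPLES)
    y <- approx(angle_series$time, angle_series$value, xout = grid,
                rule = 1, ties = "ordered")$y
    if (anyNA(y)) next
    cycles[[length(cycles) + 1L]] <-
      angle_cycle(y, outcome = outcome, side = side, cycle_index = ci,
                  system = system)
    ci <- ci + 1L
  }
  if (!length(cycles)) abort_signal("no complete cycle: all cycles discarded")
  cycles
}
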