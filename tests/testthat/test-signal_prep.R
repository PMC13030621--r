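# Synchronization, event detection, segmentation.

max_err_ms <- function(truth, detected) {
  1000 * max(vapply(truth, function(t) min(abs(detected - t)), numeric(1)))
}

test_that("impact detection finds the wand drop on the IMU stream", {
  trial <- simulate_sync_trial(2.5, seed = 3, clock_offset = 0)
  expect_equal(detect_impact_time(trial$accel), 2.5, tolerance = 0.005 / 2.5)
  # constant 1 g stream -> no impact
  flat <- data.frame(time = seq(0, 2, by = 1 / 256), ax = 0, ay = 0, az = 1)
  expect_gv_error(detect_impact_time(flat), "gv_signal_error")
  # two impacts: the argmax picks the stronger one
  tt <- seq(0, 4, by = 1 / 256)
  two <- data.frame(time = tt, ax = 0, ay = 0,
                    az = 1 + 4.1 * exp(-0.5 * ((tt - 1) / 0.01)^2) +
                      9 * exp(-0.5 * ((tt - 3) / 0.01)^2))
  expect_equal(detect_impact_time(two), 3, tolerance = 0.01 / 3)
})

test_that("drop detection finds the floor contact on the marker stream", {
  trial <- simulate_sync_trial(2.5, seed = 3)
  expect_equal(detect_drop_event(trial$marker), 2.5, tolerance = 0.01 / 2.5)
  flat <- data.frame(time = seq(0, 3, by = 0.01), z = 0.8)
  expect_gv_error(detect_drop_event(flat), "gv_signal_error")
  # time equivariance: shifting the clock shifts the event by the same amount
  shifted <- trial$marker
  shifted$time <- shifted$time + 1
  expect_equal(detect_drop_event(shifted), detect_drop_event(trial$marker) + 1,
               tolerance = 1e-9)
})

test_that("synchronize recovers offsets and drifts", {
  expect_equal(synchronize(3.0, 1.0)$offset, 2.0)
  s0 <- synchronize(c(5, 10), c(5, 10))
  expect_equal(s0$offset, 0)
  expect_equal(s0$drift, 0)
  # hand-derived two-point fit: pairs (10, 8) and (610, 607.4)
  s <- synchronize(c(10, 610), c(8, 607.4))
  expect_equal(s$offset, 2 - 0.001 * 10)
  expect_equal(s$drift, -0.001, tolerance = 1e-9)
  expect_equal(imu_to_marker_time(610, s), 607.4, tolerance = 1e-9)
  expect_gv_error(synchronize(c(1, 2), 1), "gv_pairing_error")
})

test_that("marker-based events recover ground truth and its symmetries", {
  w <- simulate_walk(n_strides = 10, seed = 18)
  mk <- w$markers
  for (s in c("left", "right")) {
    ev <- detect_events_zeni(mk[[paste0("heel_ap_", s)]],
                             mk[[paste0("toe_ap_", s)]],
                             mk$sacrum_ap, rate = 100)
    expect_lt(max_err_ms(w$truth$strikes[[s]], ev$strikes), 10)
    expect_lt(max_err_ms(w$truth$offs[[s]], ev$offs), 10)
    # direction reversal leaves the events unchanged
    rev_ev <- detect_events_zeni(-mk[[paste0("heel_ap_", s)]],
                                 -mk[[paste0("toe_ap_", s)]],
                                 -mk$sacrum_ap, rate = 100)
    expect_equal(rev_ev$strikes, ev$strikes, tolerance = 1e-9)
  }
  n <- nrow(mk)
  still <- data.frame(h = rep(0.1, n), t = rep(0.2, n), s = rep(0, n))
  expect_gv_error(detect_events_zeni(still$h, still$t, still$s, rate = 100),
                  "gv_signal_error")
})

test_that("gyroscope events recover ground truth, scale-invariantly", {
  w <- simulate_walk(n_strides = 10, clock_offset = 2.0, seed = 18)
  for (s in c("left", "right")) {
    ev <- detect_events_imu(w$imu[[s]])
    expect_lt(max_err_ms(w$truth$strikes_imu[[s]], ev$strikes), 15)
    expect_lt(max_err_ms(w$truth$offs_imu[[s]], ev$offs), 15)
    # amplitude doubling must not move the events
    doubled <- w$imu[[s]]
    doubled$gyro_sag <- 2 * doubled$gyro_sag
    ev2 <- detect_events_imu(doubled)
    expect_equal(ev2$strikes, ev$strikes, tolerance = 1e-9)
    expect_equal(ev2$offs, ev$offs, tolerance = 1e-9)
  }
  zero <- data.frame(time = seq(0, 5, by = 1 / 256), gyro_sag = 0)
  expect_gv_error(detect_events_imu(zero), "gv_signal_error")
})

test_that("synchronization recovers the generator clock model", {
  off <- 2.0; dr <- 1e-3
  trials <- lapply(c(0, 600), function(st)
    simulate_sync_trial(2.5, seed = 40 + st, clock_offset = off,
                        start_time = st, drift = dr))
  sy <- synchronize(vapply(trials, function(t) detect_impact_time(t$accel), 0),
                    vapply(trials, function(t) detect_drop_event(t$marker), 0))
  expect_lt(abs(sy$offset - off), 0.01)                      # one 100 Hz sample
  expect_lt(abs(sy$drift - (-dr / (1 + dr))) / dr, 0.1)      # within 10%
})

test_that("segmentation resamples cycles onto the 101-point grid", {
  # strikes at samples 0 and 200 of a linear ramp -> linspace(0, 20, 101)
  tser <- data.frame(time = seq(0, 2, by = 0.01),
                     value = seq(0, 20, length.out = 201))
  cyc <- segment_cycles(tser, list(strikes = c(0, 2)), outcome = "hip_flexion")
  expect_length(cyc, 1L)
  expect_equal(as.numeric(cyc[[1]]), seq(0, 20, length.out = 101),
               tolerance = 1e-9)
  # 5 strikes -> 4 cycles; constant stream -> constant cycles
  const <- data.frame(time = seq(0, 5, by = 0.01), value = 7)
  cyc5 <- segment_cycles(const, list(strikes = 0:4 + 0.5))
  expect_length(cyc5, 4L)
  expect_true(all(vapply(cyc5, function(c) all(c == 7), logical(1))))
  expect_gv_error(segment_cycles(const, list(strikes = 1)), "gv_signal_error")
  # cycles deviating > 40% from the median duration are discarded
  odd <- segment_cycles(const, list(strikes = c(0.5, 1.5, 2.5, 4.9)))
  expect_length(odd, 2L)
})

test_that("marker and gyro cycle counts agree after time alignment", {
  w <- simulate_walk(n_strides = 8, clock_offset = 1.0, seed = 26)
  mk <- w$markers
  for (s in c("left", "right")) {
    ev_m <- detect_events_zeni(mk[[paste0("heel_ap_", s)]],
                               mk[[paste0("toe_ap_", s)]],
                               mk$sacrum_ap, rate = 100)
    ev_i <- detect_events_imu(w$imu[[s]])
    matched <- gaitval:::match_event_times(
      ev_m$strikes, imu_to_marker_time(ev_i$strikes, synchronize(1, 0)),
      tol = 0.3 * median(diff(ev_m$strikes)))
    expect_gte(nrow(matched), length(w$truth$strikes[[s]]) - 1L)
    expect_lte(abs(length(ev_m$strikes) - length(ev_i$strikes)), 1L)
  }
})
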