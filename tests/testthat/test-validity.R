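# Concurrent-validity metrics and their aggregation.

test_that("pairwise metrics reproduce hand computations", {
  a <- wave(10)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a + 1, a), 1)
  d <- rep(0, 101); d[1] <- 3; d[2] <- 4
  expect_equal(rmse(a + d, a), sqrt(25 / 101))

  expect_equal(centered_rmse(a + 15, a), 0)           # pure offset removed
  expect_equal(centered_rmse(a, a), 0)
  half <- wave(5)                                      # same wave, half amplitude
  expect_equal(centered_rmse(a, half), 5 * sqrt(50 / 101))

  expect_equal(pearson_cc(2 * a + 5, a), 1)
  expect_equal(pearson_cc(-a, a), -1)
  expect_gv_error(pearson_cc(rep(3, 101), a), "gv_undefined_cc")

  expect_equal(delta_rom(a, a), 0)
  rom60 <- wave(30); rom55 <- wave(27.5)
  expect_equal(delta_rom(rom60, rom55), 5)
  expect_equal(delta_rom(a + 12, a), 0)

  expect_equal(relative_rmse(wave(30) + 6, wave(30)), 100 * 6 / 60)
  expect_equal(relative_rmse(a, a), 0)
  expect_gv_error(relative_rmse(a, rep(1, 101)), "gv_degenerate_amplitude")
})

test_that("metric pairing refuses mismatched outcomes", {
  a <- angle_cycle(wave(), "knee_flexion")
  b <- angle_cycle(wave(), "hip_flexion")
  for (f in list(rmse, centered_rmse, pearson_cc, delta_rom, relative_rmse)) {
    expect_gv_error(f(a, b), "gv_pairing_error")
  }
})

test_that("rmse decomposition identity holds for random pairs", {
  set.seed(404)
  for (i in 1:50) {
    a <- rnorm(101, sd = runif(1, 0.5, 20)) + rnorm(1, 0, 10)
    b <- rnorm(101, sd = runif(1, 0.5, 20)) + rnorm(1, 0, 10)
    r <- rmse(a, b); cr <- centered_rmse(a, b)
    expect_equal(r^2, cr^2 + (mean(a) - mean(b))^2, tolerance = 1e-9)
    expect_gte(r, cr - 1e-12)
  }
})

test_that("metrics are invariant to simultaneous side relabeling and cc to affine maps", {
  tab <- small_cohort(seed = 31)
  flipped <- as.data.frame(tab)
  flipped$side <- ifelse(flipped$side == "left", "right", "left")
  s1 <- summarize_validity(tab)
  s2 <- summarize_validity(cohort_table(flipped))
  expect_equal(s1$by_outcome$rmse, s2$by_outcome$rmse, tolerance = 1e-12)
  a <- wave(8, 0.2)
  expect_equal(pearson_cc(a, 3.7 * a - 11), 1)
})

test_that("Altman bands reproduce the printed thresholds", {
  expect_identical(interpret_cc_altman(0.51), "moderate")  # pelvis rotation
  expect_identical(interpret_cc_altman(0.15), "poor")      # knee ab/adduction
  grid <- c(-1, 0.19, 0.20, 0.39, 0.40, 0.59, 0.60, 0.79, 0.80, 1)
  expect_identical(
    interpret_cc_altman(grid),
    c("poor", "poor", "fair", "fair", "moderate", "moderate",
      "good", "good", "very good", "very good"))
  expect_gv_error(interpret_cc_altman(1.2), "gv_validation_error")
})

test_that("summarize_validity matches a brute-force aggregation oracle", {
  tab <- small_cohort(seed = 55)
  vs <- summarize_validity(tab)
  # oracle: flat per-pair recomputation with plain loops for one subject
  df <- as.data.frame(tab)
  df <- df[df$session == 1L, ]
  sid <- "CP02"
  sub <- df[df$subject_id == sid, ]
  keys <- unique(sub[sub$system == "OPTO", c("side", "cycle_index", "outcome")])
  per_outcome <- list()
  for (o in unique(keys$outcome)) {
    vals <- c()
    ko <- keys[keys$outcome == o, ]
    for (r in seq_len(nrow(ko))) {
      pick <- function(sys) as.numeric(
        sub[sub$system == sys & sub$side == ko$side[r] &
              sub$cycle_index == ko$cycle_index[r] & sub$outcome == o,
            sprintf("s%03d", 0:100)])
      vals <- c(vals, rmse(pick("IMU"), pick("OPTO")))
    }
    per_outcome[[o]] <- mean(vals)
  }
  got <- vs$by_subject[vs$by_subject$subject_id == sid, ]
  for (o in names(per_outcome)) {
    expect_equal(got$rmse[got$outcome == o], per_outcome[[o]],
                 tolerance = 1e-12)
  }
  # group means equal means of subject-level means
  manual <- aggregate(rmse ~ group + outcome, data = as.data.frame(vs$by_subject),
                      FUN = mean)
  merged <- merge(manual, as.data.frame(vs$by_outcome), by = c("group", "outcome"))
  expect_equal(merged$rmse.x, merged$rmse.y, tolerance = 1e-12)
})

test_that("null-error cohort collapses all error metrics", {
  tab <- simulate_cohort(n_as = 2, n_cp = 2, n_omd = 2, cycles_per_subject = 1,
                         seed = 9, error = null_error_model(),
                         reliability_n = NULL)
  vs <- summarize_validity(tab)
  expect_true(all(vs$by_outcome$rmse == 0))
  expect_true(all(vs$by_outcome$delta_rom == 0))
  expect_true(all(vs$by_outcome$acceptable))
})

test_that("pelvic offset cohort flags the pelvic tilt as unacceptable", {
  tab <- small_cohort(seed = 88)
  vs <- summarize_validity(tab)
  pt <- vs$by_outcome[vs$by_outcome$outcome == "pelvis_tilt", ]
  expect_true(all(pt$rmse > 10))
  expect_false(any(pt$acceptable))
  expect_true(all(pt$centered_rmse < 5))
})

test_that("rmse_vs_gps_correlation behaves at its contract boundaries", {
  tab <- small_cohort(seed = 23)
  bank <- build_normative_bank(tab, "OPTO")
  gps <- gps_table(tab, bank)[, c("subject_id", "gps")]
  res <- rmse_vs_gps_correlation(tab, gps)
  expect_setequal(res$outcome, KINEMATIC_OUTCOMES)
  expect_true(all(res$cc >= -1 & res$cc <= 1))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # constructed proportionality: replace gps by a subject's own mean RMSE
  subj <- summarize_validity(tab)$by_subject
  r_knee <- subj[subj$outcome == "knee_flexion", c("subject_id", "rmse")]
  fake <- data.frame(subject_id = r_knee$subject_id, gps = 2 * r_knee$rmse + 1)
  res2 <- rmse_vs_gps_correlation(tab, fake)
  expect_equal(res2$cc[res2$outcome == "knee_flexion"], 1, tolerance = 1e-9)
  # two subjects only -> precondition error
  two <- cohort_table(as.data.frame(tab)[as.data.frame(tab)$subject_id %in%
                                           c("AS01", "CP01"), ])
  suppressWarnings(
    expect_gv_error(rmse_vs_gps_correlation(two, gps), "gv_validation_error"))
})
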