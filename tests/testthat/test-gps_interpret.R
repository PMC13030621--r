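# Normative banks, GVS/GPS, interpretability statistics.

test_that("gait variable score matches closed forms", {
  ref <- wave(12, 0.1, 5)
  expect_equal(gait_variable_score(ref, ref), 0)
  expect_equal(gait_variable_score(ref + 3, ref), 3)
  dev <- rep(0, 101); dev[1:51] <- 4
  expect_equal(gait_variable_score(ref + dev, ref), sqrt(51 * 16 / 101))
})

test_that("GPS closed forms and brute-force oracle", {
  tab <- small_cohort(seed = 61)
  bank <- build_normative_bank(tab, "OPTO")
  curves <- bank$curves          # subject identical to the bank
  expect_equal(gps_for_side(curves, bank)$gps, 0)
  # uniform offset d on all nine curves -> GPS = d
  expect_equal(gps_for_side(curves + 2.5, bank)$gps, 2.5)
  # one curve offset 3, eight identical -> GPS = 3/3 = 1
  one <- curves; one["hip_flexion", ] <- one["hip_flexion", ] + 3
  r <- gps_for_side(one, bank)
  expect_equal(r$gps, 1)
  expect_equal(unname(r$gvs[["hip_flexion"]]), 3)
  # staged GVS aggregation equals flat enumeration of all 9 x 101 deviations
  set.seed(99)
  subject <- curves + matrix(rnorm(9 * 101, 0, 4), 9, 101)
  staged <- gps_for_side(subject, bank)$gps
  flat <- sqrt(mean((subject - bank$curves)^2))
  expect_equal(staged, flat, tolerance = 1e-12)
})

test_that("normative banks are deterministic and system/group specific", {
  tab <- small_cohort(seed = 62)
  b1 <- build_normative_bank(tab, "OPTO")
  b2 <- build_normative_bank(tab, "OPTO")
  expect_identical(b1$curves, b2$curves)
  bi <- build_normative_bank(tab, "IMU")
  # the IMU bank sits away from the OPTO bank by the configured offsets
  expect_gt(mean(bi$curves["pelvis_tilt", ] - b1$curves["pelvis_tilt", ]), 8)
  # coverage error names the missing outcome
  no_hip <- as.data.frame(tab)[as.data.frame(tab)$outcome != "hip_flexion", ]
  expect_error(build_normative_bank(cohort_table(no_hip), "OPTO"),
               "hip_flexion", class = "gv_data_error")
  expect_gv_error(gps_for_side(b1$curves[-1, ], b1), "gv_data_error")
})

test_that("MDC flags follow the strict group thresholds", {
  cfg <- analysis_config()
  expect_true(mdc_flag(2.0, "CP", cfg))
  expect_false(mdc_flag(0.5, "AS", cfg))
  expect_false(mdc_flag(1.7, "OMD", cfg))   # boundary equality does not flag
  expect_true(mdc_flag(-0.8, "AS", cfg))    # magnitude matters, not sign
  expect_gv_error(mdc_flag(1, "XX", cfg), "gv_validation_error")
})

test_that("Koo & Li bands reproduce the printed thresholds", {
  expect_identical(interpret_icc_koo(0.82), "good")
  expect_identical(interpret_icc_koo(0.13), "poor")
  grid <- c(0, 0.49, 0.50, 0.74, 0.75, 0.89, 0.90, 1)
  expect_identical(interpret_icc_koo(grid),
                   c("poor", "poor", "moderate", "moderate", "good", "good",
                     "excellent", "excellent"))
  expect_gv_error(interpret_icc_koo(1.01), "gv_validation_error")
})

test_that("Tukey outlier rule matches quartile arithmetic", {
  x <- c(a = 5, b = 5.2, c = 5.1, d = 4.9, e = 12)
  expect_identical(find_outliers(x), "e")
  expect_identical(find_outliers(rep(c(f = 5), 5)), character(0))
  expect_gv_error(find_outliers(c(1, 2, 3)), "gv_validation_error")
})

test_that("identical systems give degenerate paired comparison", {
  tab <- simulate_cohort(n_as = 4, n_cp = 3, n_omd = 3, cycles_per_subject = 1,
                         seed = 71, error = null_error_model(),
                         reliability_n = NULL)
  rep <- suppressWarnings(compare_gps_systems(tab))
  expect_equal(rep$paired$p_value, 1)
  expect_equal(rep$correlation$estimate, 1)
  expect_true(all(abs(rep$gps_by_subject$gps_imu -
                        rep$gps_by_subject$gps_opto) < 1e-12))
})

test_that("pathological groups separate from the asymptomatic group", {
  tab <- small_cohort(seed = 72)
  rep <- compare_gps_systems(tab)
  bg <- rep$gps_by_subject
  expect_gt(mean(bg$gps_opto[bg$group == "CP"]),
            mean(bg$gps_opto[bg$group == "AS"]))
  expect_gt(mean(bg$gps_opto[bg$group == "OMD"]),
            mean(bg$gps_opto[bg$group == "AS"]))
  expect_true(all(rep$by_group$gps_opto_mean > 0))
  expect_true(all(!is.na(rep$by_group$p_paired)))
})

test_that("outlier attenuation: OPTO flags severe subjects the IMU smooths over", {
  # three extreme-severity CP subjects; the IMU route shrinks deviations
  base <- simulate_cohort(n_as = 8, n_cp = 8, n_omd = 8,
                          cycles_per_subject = 1, seed = 73,
                          error = null_error_model(), reliability_n = NULL)
  df <- as.data.frame(base)
  scols <- sprintf("s%03d", 0:100)
  bank_o <- build_normative_bank(cohort_table(df), "OPTO")
  extreme <- c("CP01", "CP02", "CP03")
  sel <- df$subject_id %in% extreme
  # amplify the OPTO-side deviation of the extreme subjects
  for (o in rownames(bank_o$curves)) {
    rows <- sel & df$outcome == o & df$system == "OPTO"
    dev <- sweep(as.matrix(df[rows, scols]), 2, bank_o$curves[o, ])
    df[rows, scols] <- sweep(3 * dev, 2, bank_o$curves[o, ], `+`)
    # IMU keeps only a shrunken version of the same deviation
    rows_i <- sel & df$outcome == o & df$system == "IMU"
    df[rows_i, scols] <- sweep(1.2 * dev, 2, bank_o$curves[o, ], `+`)
  }
  rep <- compare_gps_systems(cohort_table(df))
  expect_true(all(rep$outliers$IMU %in% rep$outliers$OPTO))
  expect_gt(length(setdiff(rep$outliers$OPTO, rep$outliers$IMU)), 0L)
})
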