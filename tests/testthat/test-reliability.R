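# Discrete parameters, measurement tables, variance-component ICC.

test_that("discrete parameters match closed forms", {
  expect_equal(discrete_params(rep(5, 101)),
               c(max = 5, min = 5, rom = 0, mean = 5))
  ramp <- seq(0, 20, length.out = 101)
  expect_equal(discrete_params(ramp),
               c(max = 20, min = 0, rom = 20, mean = 10))
  p <- discrete_params(wave(7, 0.3, 2)); pf <- discrete_params(-wave(7, 0.3, 2))
  expect_equal(pf[["max"]], -p[["min"]])
  expect_equal(pf[["min"]], -p[["max"]])
  expect_equal(pf[["rom"]], p[["rom"]])
})

test_that("reliability tables implement the intra/inter designs", {
  tab <- small_cohort(seed = 41)
  intra <- reliability_table(tab, "intra")
  inter <- reliability_table(tab, "inter")
  # intra: sessions 1 and 2 with operator A; inter: both operators, session 2
  expect_setequal(unique(intra$condition), c(1L, 2L))
  # only reliability-subset subjects have both conditions
  expect_setequal(unique(intra$subject_id),
                  c("AS01", "AS02", "AS03", "CP01", "CP02", "OMD01", "OMD02"))
  expect_setequal(unique(inter$subject_id), unique(intra$subject_id))
  # one value per subject x condition x outcome x system x parameter
  expect_equal(anyDuplicated(intra, by = c("subject_id", "outcome", "system",
                                           "parameter", "condition")), 0L)
  # session-1-only data cannot support either design
  s1 <- as.data.frame(tab)[as.data.frame(tab)$session == 1L, ]
  expect_gv_error(reliability_table(cohort_table(s1), "inter"),
                  "gv_design_error")
  expect_gv_error(reliability_table(cohort_table(s1), "intra"),
                  "gv_design_error")
})

test_that("fit_icc recovers degenerate structures", {
  # pure between-subject spread, no noise -> ICC ~ 1
  m <- simulate_measurement_table(30, 9, 0, 1e-8, seed = 1)
  expect_gt(fit_icc(m)$icc, 0.999)
  # pure noise -> ICC near 0
  m0 <- simulate_measurement_table(60, 0, 0, 1, seed = 2)
  expect_lt(fit_icc(m0)$icc, 0.2)
  expect_gv_error(fit_icc(simulate_measurement_table(4, 1, 0, 1, seed = 3)),
                  "gv_validation_error")
})

test_that("REML and method-of-moments estimators agree on balanced tables", {
  m <- simulate_measurement_table(40, 9, 0.5, 0.5, seed = 8)
  r_reml <- fit_icc(m)
  expect_identical(r_reml$method, "reml")
  wide <- t(matrix(m$value[order(m$condition, m$subject)], ncol = 2))
  mom <- gaitval:::anova_components(t(wide))
  expect_equal(r_reml$sigma2_subject, mom$sigma2_subject, tolerance = 1e-6)
  expect_equal(r_reml$sigma2_residual, mom$sigma2_residual, tolerance = 1e-6)
  expect_equal(r_reml$sigma2_class, mom$sigma2_class, tolerance = 1e-6)
})

test_that("ICC is monotone in subject variance and bounded", {
  iccs <- vapply(c(0.5, 2, 5, 9, 20), function(s2) {
    fit_icc(simulate_measurement_table(80, s2, 0.5, 0.5, seed = 11))$icc
  }, numeric(1))
  expect_true(all(diff(iccs) > 0))
  expect_true(all(iccs >= 0 & iccs <= 1))
})

test_that("variance components are recoverable from generated cohorts", {
  spec <- variance_spec(subject = 9, session = 2, operator = 0.5,
                        cycle = 0, residual = 0.5)
  # asymptomatic subjects only: pathology deviation mixtures would add
  # group-specific between-subject variance on top of the specified one.
  # The class component has one effective degree of freedom per cohort, so
  # recovery is checked on the mean estimate across three seeds.
  est <- sapply(19:21, function(sd) {
    tab <- simulate_cohort(n_as = 200, n_cp = 1, n_omd = 1,
                           cycles_per_subject = 1, seed = sd,
                           error = null_error_model(), variance = spec,
                           outcomes = "pelvis_obliquity",
                           reliability_n = c(AS = 200, CP = 0, OMD = 0),
                           stride_waveform_rms = 0)
    meas <- reliability_table(tab, "intra")
    m <- meas[meas$parameter == "mean" & meas$system == "OPTO", ]
    r <- fit_icc(m[, c("subject_id", "condition", "value")])
    c(r$sigma2_subject, r$sigma2_class, r$sigma2_residual)
  })
  avg <- rowMeans(est)
  expect_lt(abs(avg[1] - 9), 0.15 * 9)
  expect_lt(abs(avg[2] - 2), 0.15 * 2)
  expect_lt(abs(avg[3] - 0.5), 0.15 * 0.5)
})

test_that("reliability_summary shapes the plane x joint x parameter table", {
  tab <- small_cohort(seed = 42)
  res <- reliability_summary(tab, "intra")
  expect_equal(nrow(res), 11L * 2L * 4L)  # outcomes x systems x parameters
  expect_setequal(unique(res$plane), c("sagittal", "frontal", "transverse"))
  expect_true(all(res$icc >= 0 & res$icc <= 1))
  expect_true(all(res$band %in% c("poor", "moderate", "good", "excellent")))
})
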