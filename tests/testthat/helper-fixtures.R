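# Shared fixtures: all generated in code, no stored data.

t_grid <- seq(0, 1, length.out = 101)

# A deterministic non-constant curve with known shape.
wave <- function(amplitude = 10, phase = 0, mean_level = 0) {
  mean_level + amplitude * sin(2 * pi * (t_grid - phase))
}

# Minimal hand-built cohort rows: one subject/side/outcome pair per system,
# with explicitly chosen sample values.
tiny_cohort <- function(opto, imu, outcome = "knee_flexion",
                        subject_id = "AS01", group = "AS", side = "left") {
  row <- function(system, samples) {
    cbind(data.frame(subject_id = subject_id, group = group,
                     age_group = "adult", session = 1L, operator = "A",
                     system = system, side = side, cycle_index = 0L,
                     outcome = outcome),
          as.data.frame(as.list(setNames(samples, sprintf("s%03d", 0:100)))))
  }
  cohort_table(rbind(row("OPTO", opto), row("IMU", imu)))
}

# Small seeded cohort reused across tests (cheap: 1 cycle, few subjects).
small_cohort <- function(seed = 101, ...) {
  simulate_cohort(n_as = 3, n_cp = 3, n_omd = 3, cycles_per_subject = 2,
                  seed = seed, reliability_n = c(AS = 3, CP = 2, OMD = 2), ...)
}

expect_gv_error <- function(expr, class) expect_error(expr, class = class)
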