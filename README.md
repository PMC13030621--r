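# gaitval

Agreement, reliability and interpretability analysis for paired-system
gait kinematics.

## The problem

Clinical gait analysis quantifies lower-limb joint angles (pelvis, hip,
knee, ankle, foot progression) across the gait cycle, conventionally with
an optoelectronic motion-capture system. Wearable inertial measurement
units (IMUs) can estimate the same curves cheaply and outside the
laboratory — but before an IMU pipeline is used on patients, three
measurement properties must be demonstrated against the reference:

* **concurrent validity** — per-cycle RMSE, centered RMSE (offset removed),
  Pearson correlation and ΔROM between matched curves, aggregated cycle →
  subject → group and read against a 5° clinical acceptability threshold
  and Altman's correlation bands;
* **reliability** — intra-operator (two sessions, one operator) and
  inter-operator (one session, two operators) intraclass correlation
  coefficients of discrete curve parameters (max, min, ROM, mean), from
  the variance components of a two-way mixed-effects model
  `ICC = σ²_subject / (σ²_subject + σ²_class + σ²_residual)`,
  read with Koo & Li's bands;
* **interpretability** — the Gait Profile Score
  `GPS = sqrt(mean of 9 GVS²)`, where each Gait Variable Score
  `GVS = sqrt(mean over the cycle of (curve − normative mean)²)`
  is computed against a system-specific normative bank (the asymptomatic
  group's mean curves *for that system*), compared between systems with
  paired tests/correlation and read against minimal detectable changes
  (0.7° asymptomatic, 1.7° pathological).

`gaitval` implements this evaluation end to end for a three-group cohort
(asymptomatic AS, cerebral palsy CP, other motor disorders OMD), plus the
upstream signal stages — wand-drop clock synchronization, marker-based
(coordinate) and gyroscope-based gait event detection, strike-to-strike
segmentation onto the 101-point gait-cycle grid — and a seeded synthetic
cohort generator with a controlled between-system error structure, so the
whole pipeline is testable without any recorded data.

## Worked example

```r
library(gaitval)

tab <- simulate_cohort(seed = 1)   # 55 subjects, 2 systems, 11 outcomes
vs  <- summarize_validity(tab)
vs$overall
#>     group  rmse centered_rmse    cc delta_rom
#> 1:     AS  7.67          2.55 0.825      3.99
#> 2:     CP  7.45          2.58 0.852      3.87
#> 3:    OMD  7.69          2.56 0.895      3.86
```

Mean RMSE sits near 7–8° while the centered RMSE stays near 2.5°: the
between-system error is dominated by a constant angular offset (15° at
pelvic tilt in the generator's error model, from the mismatch between the
inertial neutral-pelvis definition and the marker model), while the
waveform itself agrees well (CC > 0.8).

```r
rep <- compare_gps_systems(tab)
rep$by_group[, .(group, gps_opto_mean, gps_imu_mean, p_paired, exceeds_mdc)]
#>     group gps_opto_mean gps_imu_mean p_paired exceeds_mdc
#> 1:     AS          4.51         5.49 0.002676        TRUE
#> 2:     CP          7.82         8.32 0.131317       FALSE
#> 3:    OMD          6.65         7.51 0.000552       FALSE
```

The asymptomatic group scores a GPS near the ≈5° normal value on both
systems and the pathological groups sit well above it. The AS difference
(0.98°) exceeds that group's 0.7° minimal detectable change — in tight,
homogeneous normal gait even a small methodological bias is detectable —
while the CP difference stays inside the pathological 1.7° MDC.

```r
rel <- reliability_summary(tab, "intra")
rel[outcome == "pelvis_tilt" & parameter == "mean",
    .(plane, joint, parameter, system, icc, band)]
#>       plane  joint parameter system  icc      band
#> 1: sagittal pelvis      mean    IMU 0.86      good
#> 2: sagittal pelvis      mean   OPTO 0.96 excellent
```

Sensor re-placement between conditions costs the IMU system reliability
relative to the marker reference, as expected.

A command-line interface wraps the same stages:

```sh
Rscript inst/cli/gaitval simulate --out sim --seed 7
Rscript inst/cli/gaitval analyze --in sim/cycles.csv --out results
Rscript inst/cli/gaitval analyze --in sim --out results_raw   # raw streams
```

`analyze` emits `validity_summary.csv`, `reliability_icc.csv`,
`gps_report.csv`, a markdown report and a run manifest; exit codes are 0
(success), 2 (validation error), 3 (data/pairing error).

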