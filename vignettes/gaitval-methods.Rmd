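---
title: "Methods: agreement, reliability and interpretability of paired-system gait kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement, reliability and interpretability of paired-system gait kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Clinical gait analysis quantifies lower-limb joint kinematics — pelvis, hip,
knee and ankle angles across the gait cycle — conventionally with an
optoelectronic (camera + reflective marker) system, the clinical reference.
Wearable inertial measurement units (IMUs) promise the same curves outside
the laboratory, but before an IMU pipeline can be used clinically its output
must be shown to be *valid* (it agrees with the reference), *reliable* (it
repeats across sessions and operators) and *interpretable* (summary scores
derived from it carry the same clinical meaning). `gaitval` implements that
three-part evaluation as a reusable, fully tested pipeline, together with
the upstream signal steps (clock synchronization, gait event detection,
cycle segmentation) and a seeded synthetic cohort generator that stands in
for a study population.

All angle curves are handled time-normalized to 101 samples (0–100% of the
gait cycle, inclusive) in degrees. Lab protocols rarely print their
normalization grid; 101 points is the community convention and makes
percent indices integral, so it is fixed here, with linear interpolation as
the documented resampling rule.

## Concurrent validity

For every matched cycle pair (same subject, session, side, cycle index and
outcome; one curve per system) the pipeline computes:

* **RMSE** — root mean square pointwise difference (degrees);
* **centered RMSE** — RMSE after removing each curve's own cycle mean. The
  analytic identity `rmse² = centered_rmse² + (mean difference)²` links the
  two and is enforced by tests to 1e-9: the centered variant isolates
  waveform error from the constant angular offset that dominates
  IMU-vs-marker disagreement (anatomical-frame definition mismatches,
  e.g. a ≈15° pelvic tilt offset when no calibration posture aligns the
  sacral sensor with the marker-model pelvis);
* **Pearson correlation** over the 101 points, read with Altman's bands
  (poor < 0.20 ≤ fair < 0.40 ≤ moderate < 0.60 ≤ good < 0.80 ≤ very good);
* **ΔROM** — absolute difference in range of motion;
* **relative RMSE** — 100 · RMSE / ROM of the reference curve. Relative
  error conventions vary (percent of amplitude, of mean ROM, of a normative
  range); we implement the literal percent-of-reference-amplitude
  definition and document it as such.

Aggregation is fixed by contract: cycle-level metrics are averaged over a
subject's cycles and sides (unweighted, both sides pooled — this prevents
subjects with more recorded cycles from dominating), then summarized per
group × outcome as the mean across subjects with a 95% t-interval
half-width. Group RMSE means are flagged against a 5° clinical
acceptability threshold. Undefined correlations (constant curves) exclude
the pair from the correlation average only, and are logged.

## Reliability

Reliability is computed on discrete curve parameters (maximum, minimum,
range of motion, mean), cycle-averaged per subject and condition:

* *intra-operator*: operator A's sessions one week apart;
* *inter-operator*: operators A and B within session 2.

Sides are pooled with the cycles before fitting (side handling is rarely
reported in reliability protocols; pooling is our documented choice). The model is
`value ~ condition + (1 | subject)` fit by REML — a two-way mixed model
with the two-level class (session or operator) fixed, a random subject
intercept, and no subject × condition interaction (unidentifiable with one
value per cell). The class variance is estimated from the fitted condition
contrast corrected for residual sampling error (`Δ²/2 − σ²ᵣ/n`, the
balanced-ANOVA estimator), negative estimates are truncated at zero, and

ICC = σ²_subject / (σ²_subject + σ²_class + σ²_residual)

— a two-way mixed, absolute-agreement, single-measurement form (including
the class variance in the denominator is what makes the coefficient
"absolute agreement"). If the mixed-model fit
fails, a balanced-ANOVA method-of-moments fallback is used and flagged;
on balanced tables with interior estimates the two coincide (tested to
1e-6). ICCs are read with Koo & Li's bands (poor < 0.50 ≤ moderate < 0.75 ≤
good < 0.90 ≤ excellent).

## Interpretability: the Gait Profile Score

The Gait Variable Score (GVS) of one angle is the RMS deviation of a
subject's curve from a normative mean curve; the Gait Profile Score (GPS)
is the RMS of the nine GVS values (pelvis and hip in three planes, knee and
ankle sagittal, foot progression). Because all curves share the 101-point
grid, the RMS-of-GVS and flat RMS-over-all-909-deviations readings of the
verbal definition coincide; tests assert this to 1e-12. Each system gets
its own normative bank — the pointwise mean of the asymptomatic group's
session-1 cycles *measured by that system* — so a constant between-system
offset does not by itself inflate the IMU GPS. GVS is computed on the
subject-side mean curve (the score is reported once per side, not per
cycle; per-cycle averaging is the other defensible reading and is
documented as not taken).

The interpretability statistics mirror a method-comparison analysis:
paired between-system test on side-averaged GPS (t-test or Wilcoxon),
between-system correlation (Pearson or Spearman), per-group paired
Wilcoxon tests with Bonferroni correction, Kruskal–Wallis group comparison
with pairwise Bonferroni-adjusted Wilcoxon tests, and a reading of each
group's mean GPS difference against minimal detectable changes (1.7° for
pathological groups, 0.7° for asymptomatic; strict inequality — the MDC is
the smallest change *beyond* measurement error, so boundary equality does
not flag). Normality is decided by Shapiro–Wilk at α: visual histogram
assessment is common practice, but a pipeline needs a reproducible rule; a
`nonparametric` switch forces the rank-based branch. Tukey's 1.5 × IQR rule
flags per-system GPS outliers, supporting the check that extreme reference
deviations are attenuated by the inertial route.

## Signal preparation

No hardware synchronization is assumed. Wand-drop trials provide a shared
impact event: on the IMU side the global maximum of |‖a‖ − 1 g| above a 4 g
threshold; on the marker side the peak downward velocity at the end of the
descent, refined by sub-sample interpolation of the near-floor crossing
(any smoothing of the kinked trajectory biases the contact time early —
the tested estimator is accurate to well under one 100 Hz sample). One
trial gives the clock offset; trials at session start and end identify a
linear drift. `drift` is reported as the rate of the marker clock relative
to the IMU clock minus one, so IMU times map to the marker clock as
`marker = imu·(1 + drift) − offset`.

Marker-based events follow the coordinate method: foot strikes at local
maxima of the heel-to-sacrum anteroposterior distance along the walking
direction, foot offs at local minima of the toe-to-sacrum distance, with
the direction sign estimated per pass so back-and-forth walkway passes are
both processed (events are invariant under direction reversal). The
inertial detector is a single-channel sagittal-gyroscope variant of
foot-worn event detection: dominant positive mid-swing peaks (threshold:
40% of the median candidate peak), foot strike as the first post-peak
local minimum below an adaptive negative threshold, foot off as the last
pre-peak one — all thresholds relative, so event times are invariant under
amplitude scaling. Detector thresholds and filter settings are our own
documented defaults for standard gait bandwidths: zero-phase 2nd-order
Butterworth low-passes at 10 Hz (markers) and 17 Hz (gyroscope).

Cycles run strike-to-strike, linearly resampled to 101 points; cycles
deviating more than 40% from the median duration are discarded and logged
(the automated stand-in for the manual event checking of a lab workflow).
Because the two systems use *different* event sources — deliberately, to
match stand-alone IMU use — cycles are paired by order of matched strikes:
after synchronization, strikes detected by the two routes are matched
within 30% of a stride and the k-th matched cycle pairs with the k-th.

## The synthetic cohort: a stated world

The generator emulates a three-group validation-study design: 55 subjects
(15 asymptomatic AS, 15 cerebral palsy CP, 25 other motor disorders OMD,
with a fixed child/teen/adult layout), 11 outcomes, both sides, five cycles
per side and condition, and a 27-subject reliability subset (13/7/7)
measured twice in session 2. One seeded RNG stream per `simulate_*` call
makes every output bit-reproducible.

An optoelectronic curve is: template + smooth subject gait signature +
group pathology field × per-subject severity (mean 1, SD 0.25) + constant
subject/session/operator/cycle offsets from the variance specification +
smooth stride-to-stride waveform variability (RMS 1°). The CP field is a
fixed crouch/equinus-flavoured deviation shape; OMD subjects draw
heterogeneous per-subject random deviation mixtures — neither models a
specific diagnosis; their RMS scales are calibrated once so the AS group
scores a GPS near the ≈5° normal value and the pathological groups sit
2–3.5° above it, a clinically typical group separation. Session and operator
effects are generated as exact ± contrasts whose sample variance equals
the stated component: with only two levels a random draw would make the
class variance a one-degree-of-freedom lottery and parameter recovery
untestable.

The matched IMU curve adds a constant angular offset (subject-level mean —
15° at pelvic tilt, 6° elsewhere — plus a per-condition sensor-placement
draw and per-cycle jitter) and waveform noise: a smooth correlated
component scaled per anatomical plane (transverse worst) plus white sample
noise. Setting all offsets to zero and giving both systems iid smooth
noise (`opto_noise_sd = noise_sd`) yields two exchangeable systems — the
null world used for the type-I-error check of the paired GPS test. The
optional small time-warp mentioned as a possible extension of the error
model is not implemented; a constant offset plus waveform noise already
reproduces the offset-dominated error structure that motivates the
centered RMSE.

What a green test does **not** establish: the generator has no
biomechanically consistent dynamics, no soft-tissue artifact physics, no
turns, no diagnosis-specific gait signatures, and its waveform noise is
stationary — so passing tests certify the *statistical machinery*
(metrics, models, detectors, aggregation), not the clinical performance of
any real sensor fusion method, which is out of scope along with the
marker-model and sensor-to-segment mathematics.

Raw-walk recordings are likewise idealized: straight-line progression,
strictly periodic strides, heel/toe excursions whose extrema coincide with
ground-truth events by construction, and gyroscope traces built from
Gaussian lobes (mid-swing positive, strike/off negative) at the true event
times. Ground-truth event lists keep only events detectable by both
detector families (far enough from the recording edges); boundary extrema
may legitimately be detected without a ground-truth partner and are
absorbed by the time-aligned pairing.

## Numerical choices and degenerate inputs

* Correlations of constant curves are undefined: scalar calls raise a
  classed error; table-level aggregation excludes and logs the pair.
* Relative RMSE requires a reference amplitude above 1°.
* Negative variance estimates truncate to zero before the ICC, keeping it
  in [0, 1].
* Paired tests on identical score vectors return p = 1 (the no-difference
  region) instead of erroring inside the rank test.
* Band functions use inclusive lower bounds exactly as printed.
* Two sync events closer than 1 s are treated as replicates (offset
  averaged, drift undefined) rather than fitting a wildly ill-conditioned
  line.
* CSV writing sorts by the full key, making files a pure function of table
  content; sample values survive a round trip to at least 12 significant
  digits.

## Known limitations

The acceptance evaluation is property-based by design: the package ships
no recorded reference data set, so numeric agreement with any particular
laboratory's results is out of scope. The ICC model fixes
the two-level class; a fully random class with two levels is statistically
unidentifiable anyway, but readers comparing against ICC(2,1) software
should expect small differences. The reliability stage models
session/operator as the only class components — carry-over, marker
re-placement drift within a session, and operator × subject interactions
are not separable in this design and are absorbed by the residual.
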