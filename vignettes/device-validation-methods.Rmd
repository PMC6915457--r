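---
title: "Validating a blood pressure monitor: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a blood pressure monitor: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eshval)
```

## The validation problem

Automated cuff monitors estimate blood pressure oscillometrically rather
than by auscultation, and their accuracy varies across populations —
particularly where arterial stiffness alters the oscillometric signal, as
in elderly or renal patients. The 2010 revision of the European Society of
Hypertension International Protocol (ESH-IP2) is the standard procedure for
deciding whether a device agrees well enough with a reference to be
recommended for self-measurement. `eshval` implements that analysis as a
reusable package: the nine-reading measurement schedule, the
flanking-reference pairing with favorable selection, the cumulative band
classification, the three-part grading for systolic pressure (SBP),
diastolic pressure (DBP) and a heart-rate (HR) extension, and Bland–Altman
agreement summaries, together with a synthetic-data generator so that every
stage is testable without access to patient measurements.

## Measurement schedule and pairing

Each of the 33 subjects contributes nine consecutive cuff readings taken
30–60 s apart, alternating devices:

* BPA (reference, entry reading) and BPB (test, device-detection reading) —
  acquisition readings, retained in the data model but never graded;
* BP1, BP3, BP5, BP7 on the reference device and BP2, BP4, BP6 on the test
  device — the graded schedule.

Because the devices never measure simultaneously, each test reading is
compared with *both* flanking reference readings — BP2 with BP1 and BP3,
BP4 with BP3 and BP5, BP6 with BP5 and BP7 — and the comparison more
favorable to the device (the smaller absolute difference) is kept. That
yields 3 comparisons per subject and 99 per parameter. Differences are
signed test − reference; both devices display integers, so readings are
stored as integers and every difference is exact — there is no
floating-point ambiguity at a band edge.

Two aspects of favorable selection are underdetermined by the protocol's
one-sentence description, and we fixed them as follows:

* **Ties** between the two flanks go to the *preceding* reference. The
  choice never affects band counts (the absolute difference is equal either
  way); it only fixes which reference value is recorded.
* **Per-parameter independence.** Each parameter (SBP, DBP, HR) selects its
  own flank. This is the default because the banded counts are computed per
  parameter. A `selection_mode = "joint"` option instead forces SBP and DBP
  onto the single flank minimizing `|dSBP| + |dDBP|` (HR stays independent),
  for sensitivity analysis; the mode in force is echoed in the report's
  provenance block.

## Grading

Differences are classified into three cumulative bands — within 5, 10, 15
mm Hg for BP; within 3, 5, 8 bpm for HR — where *within* is inclusive: a
difference of exactly 5 mm Hg is within 5 mm Hg. With integer differences
this convention is unambiguous.

* **Part 1** pools the 99 comparisons. Each band has two requirements: the
  higher counts (73/87/96) must be met in at least two of the three bands,
  and the lower counts (65/81/93) in all three.
* **Part 2** grades subjects: at least 24 of the 33 must have ≥ 2 of their
  3 differences within the first band (5 mm Hg or 3 bpm), and at most 3 may
  have none within it. The HR extension reuses the same subject criteria.
* **Part 3** is a conjunction: the BP grade combines Part 1 and Part 2 for
  SBP *and* DBP; HR has its own Part 3 from its Part 1 and Part 2 alone.

The graders are pure functions of the counts, so the requirement boundaries
can be recovered by brute-force search over count configurations — which is
exactly how the test suite checks them against a truth-table oracle.

The original protocol also contains observer-training and entry-pressure
distribution requirements; they concern study conduct rather than the
recorded nine-reading sequences and are out of scope here.

### Non-standard cohort sizes

`grade_device()` expects 33 subjects. Any other size triggers a warning and
proportional rescaling of the requirement counts (minima rounded up, maxima
rounded down), which keeps the required *fractions* intact. This is a
pragmatic extension for exploratory use — a rescaled grade is not an
ESH-IP2 grade, and the report's provenance block makes the rescaling
visible.

## Agreement statistics

The headline bias is the mean signed difference (test − reference), with
limits of agreement at bias ± 1.96 SD (sample SD, configurable multiplier).
The mean absolute difference is reported alongside, clearly labelled, since
validation summaries are sometimes read either way. Bland–Altman points
take the mean of the paired test and reference values on the abscissa and
the signed difference on the ordinate; no regression-based proportional
bias correction is applied, matching standard practice for these reports.
Agreement is computed on the favorably-selected pairs — the same
comparisons that are graded.

## The synthetic-data generator

The generator's role is to exercise the analysis under controlled
conditions, not to be a physiological simulator. It has three layers:

* **Cohort** (`cohort_model()`): per-sex truncated-normal distributions for
  age, weight, height and arm circumference, with defaults matching the
  study population's summary statistics (e.g. age 71.0 (SD 11.2) years, arm
  circumference 267 (SD 31) mm overall; 18 male / 15 female allocated
  deterministically). BMI is derived from weight and height, never drawn.
  About 1 subject in 11 is assigned a left-arm measurement, mirroring the
  study's rate of right-arm contraindications. Measurement arm and rest
  metadata are annotations; they never gate grading.
* **Physiology** (`physiology_model()`): subject-level true SBP drawn
  N(135, 20²) mm Hg, DBP correlated with SBP (r = 0.6) around N(75, 12²)
  and constrained at least 10 mm Hg below it, HR N(72, 10²) bpm. These
  level distributions are working placeholders — the study reports no BP or
  HR levels for its cohort — chosen as typical of an elderly hypertensive
  population. Within a subject, each of the nine epochs receives
  independent jitter (SD 4 / 3 / 3 for SBP / DBP / HR) plus an optional
  linear drift (default zero). The jitter defaults are stated constants
  chosen so that both passing and failing devices are reachable regimes;
  epoch-level truth is constrained to keep SBP at least 2 mm Hg above DBP
  so integer rounding can never invert a reading.
* **Device error** (`device_error_model()`): per-parameter additive bias,
  proportional bias and Gaussian noise, applied independently by the
  reference and test devices, then rounded to the displayed integer.
  Readings falling outside physiologic ranges are re-drawn a bounded number
  of times, then rejected. The default is an error-free device; study-like
  error models are set explicitly where used (see `analysis/`).

Random streams are split per subject (a deterministic sub-seed per subject
and stream), so appending subjects never perturbs earlier subjects' draws,
and replicate seeds in `pass_probability()` are shared across configurations
— comparisons between device models are paired by common random numbers.

What the generator does **not** emulate: oscillometric waveform artefacts,
arm-circumference-dependent cuff error, arterial-stiffness-specific error
structure, observer effects, or any dependence of device error on the true
pressure beyond the optional proportional term. Tests passing on synthetic
data therefore demonstrate the *analysis* is correct under the stated error
model, not that any physical device is accurate.

### Degenerate and edge regimes

* Zero device error *and* zero within-subject variability make the test
  device read exactly what the reference reads: every difference is 0 and
  all parts pass deterministically. This is the identity case the test
  suite pins down. With the default within-subject jitter, an error-free
  device still faces genuine reading-to-reading variability, and a rare
  unlucky cohort can miss a band requirement — which is a property of the
  protocol itself, not an artefact.
* A constant +20 mm Hg systolic bias puts every SBP difference beyond the
  15 mm Hg band, so Part 1 fails with certainty.
* With zero within-subject variability and an error-free reference, both
  flanking references are identical, favorable selection is inert, and the
  mean signed difference is an unbiased estimate of the configured test
  bias — the regime used for bias-recovery checks. With noise or jitter
  present, favorable selection shrinks the spread of the kept differences;
  summaries describe the selected comparisons, as in the protocol itself.

## Problem sizes

The Monte-Carlo checks use 100 replicate studies per configuration (33
subjects each) for pass-probability estimates, a 3,334-subject study
(10,002 comparisons) for bias recovery, and 10,000 simulated differences
for limits-of-agreement coverage; exact binomial (Clopper–Pearson)
intervals accompany every estimated probability. The power analysis in
`analysis/04_pass_probability.R` varies test-device noise over
0–8 mm Hg at zero within-subject variability, where the paired
common-random-numbers design makes the estimated pass curve monotone by
construction.

## Known limitations

* The entry-BP distribution requirements of the full protocol (recruitment
  ranges for low/medium/high pressure) are not modelled; the generator
  draws one cohort-level pressure distribution.
* The rescaled grading for n ≠ 33 is an extrapolation, flagged by a warning
  and the provenance block.
* Agreement summaries inherit the favorable-selection shrinkage; they are
  not estimates of free-living device error.
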