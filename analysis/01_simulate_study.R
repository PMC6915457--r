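#!/usr/bin/env Rscript
# Step 1 — generate a synthetic validation study.
#
# The cohort reproduces the published demographic structure (33 subjects,
# 18 male / 15 female, elderly hemodialysis population). The test device is
# given a modest positive bias near the published mean differences
# (SBP 4.03 mm Hg, DBP 2.43 mm Hg, HR 1.93 bpm) plus measurement noise —
# an imperfect but plausible consumer device. Whether it passes the
# protocol is for step 2 to decide. Output feeds steps 2-4.

suppressPackageStartupMessages(library(eshval))

seed <- 101L
dir.create("results", showWarnings = FALSE)

test_device <- device_error_model(
  bias = c(sbp = 4, dbp = 2.4, hr = 1.9),
  noise_sd = c(sbp = 3, dbp = 3, hr = 2)
)
reference_device <- device_error_model(noise_sd = c(sbp = 2, dbp = 2, hr = 1))

study <- simulate_study(
  cohort = cohort_model(),
  physiology = physiology_model(),
  reference_device = reference_device,
  test_device = test_device,
  seed = seed
)

write_study(study, "results/measurements.csv", "results/roster.csv")

cat("Simulated", nrow(study$roster), "subjects,",
    nrow(study$measurements), "readings (seed", seed, ")\n")
cat("Sex split:", sum(study$roster$sex == "male"), "male /",
    sum(study$roster$sex == "female"), "female\n")
cat("Wrote results/measurements.csv and results/roster.csv\n")
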