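#!/usr/bin/env Rscript
# Step 2 — run the full grading analysis on the study from step 1:
# cohort screening, favorable flanking pairing, cumulative band counts,
# Part 1 / Part 2 per parameter, the joint BP Part 3 and the HR Part 3.
# Writes the canonical JSON report and its markdown rendering.

suppressPackageStartupMessages(library(eshval))

study <- read_study("results/measurements.csv", "results/roster.csv")
validation <- grade_device(study$measurements, study$roster)

print(validation$screening)
print(validation)

write_report(validation, "results/validation_report.json",
             "results/validation_report.md")
cat("Wrote results/validation_report.{json,md}\n")
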