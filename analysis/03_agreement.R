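#!/usr/bin/env Rscript
# Step 3 — Bland-Altman agreement for each parameter: per-comparison
# mean/difference points with bias and limits of agreement. Point data go
# to CSV (so any plotting layer can redraw the figures); rendered plots go
# to results/figures/.

suppressPackageStartupMessages({
  library(eshval)
  library(dplyr)
})

study <- read_study("results/measurements.csv", "results/roster.csv")
diffs <- all_differences(study$measurements)

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
all_points <- list()
for (p in c("sbp", "dbp", "hr")) {
  ba <- bland_altman(diffs[diffs$parameter == p, ])
  s <- ba$summary
  cat(sprintf("%s: bias %.2f (SD %.2f), LoA [%.2f, %.2f]\n",
              toupper(p), s$mean_signed_difference, s$sd_signed_difference,
              s$loa_lower, s$loa_upper))
  all_points[[p]] <- ba$points
  ggplot2::ggsave(sprintf("results/figures/bland_altman_%s.png", p),
                  plot(ba), width = 5, height = 4, dpi = 150)
}

readr::write_csv(bind_rows(all_points), "results/bland_altman_points.csv")
cat("Wrote results/bland_altman_points.csv and results/figures/*.png\n")
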