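#!/usr/bin/env Rscript
# Stage 3 — score every patient's Fragility Score.
#
# Simulates one RF scan per patient from their latent fragility and runs
# the full FS pipeline (envelope, interface segmentation, ROI selection,
# per-segment spectra, correlation classification against the patient's
# stratum-matched models, ROI-mean aggregation). Appends the `fs` column.
# Requires stages 1-2.

suppressPackageStartupMessages(library(remsfs))
seed <- 20260922L

for (site in c("lumbar", "femur")) {
  co <- read_cohort_csv(sprintf("results/cohort_%s.csv", site))
  db <- read_reference_db(sprintf("results/refdb_%s.json", site))
  t0 <- Sys.time()
  co <- score_cohort(co, db, seed = derive_seed(seed, 20L + nchar(site)))
  cat(sprintf("%s: scored %d patients in %.0f s; FS median %.1f (IQR %.1f-%.1f)\n",
              site, nrow(co), as.numeric(Sys.time() - t0, units = "secs"),
              median(co$fs), quantile(co$fs, 0.25), quantile(co$fs, 0.75)))
  fx <- co$fs[co$fractured]; nf <- co$fs[!co$fractured]
  cat(sprintf("  fractured FS median %.1f vs non-fractured %.1f (Mann-Whitney p = %.2g)\n",
              median(fx), median(nf), mann_whitney_u(fx, nf)$p_two_sided))
  data.table::fwrite(co, sprintf("results/cohort_%s_scored.csv", site))
}
cat("scored cohorts written to results/cohort_{lumbar,femur}_scored.csv\n")
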