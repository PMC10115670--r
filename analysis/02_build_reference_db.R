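#!/usr/bin/env Rscript
# Stage 2 — build the stratified reference databases.
#
# For every (sex, 5-year age bin, BMI class, site) stratum present in the
# simulated cohorts, simulates a reference category of 100 subjects (half
# with fractures, half without), runs the FS spectral front-end on each
# scan and stores the per-stratum mean frail / non-frail model spectra.
# Requires stage 1 outputs.

suppressPackageStartupMessages(library(remsfs))
seed <- 20260922L

for (site in c("lumbar", "femur")) {
  co <- read_cohort_csv(sprintf("results/cohort_%s.csv", site))
  strata <- cohort_strata(co)
  cat(sprintf("%s: %d strata x 100 reference subjects ...\n",
              site, nrow(strata)))
  t0 <- Sys.time()
  db <- build_reference_database(strata, n_per_category = 100L,
                                 seed = derive_seed(seed, 10L + nchar(site)))
  cat(sprintf("  built in %.0f s\n",
              as.numeric(Sys.time() - t0, units = "secs")))
  write_reference_db(db, sprintf("results/refdb_%s.json", site))
}
cat("reference databases written to results/refdb_{lumbar,femur}.json\n")
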