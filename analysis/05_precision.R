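#!/usr/bin/env Rscript
# Stage 5 — intra- and inter-operator repeatability of FS.
#
# Runs the densitometric precision design at each site: 15 patients, three
# repeated scans each (45 cases per arm). Intra-operator repeats share one
# operator; inter-operator repeats rotate over three operators, one
# experienced and two newly trained, whose probe-handling offsets add an
# operator-level variance component. Reports RMS-CV with its 95% upper
# confidence bound.

suppressPackageStartupMessages({library(remsfs); library(jsonlite)})
seed <- 20260922L

out <- list()
for (site in c("lumbar", "femur")) {
  for (mode in c("intra", "inter")) {
    r <- run_precision_experiment(site, mode, m = 15, k = 3,
                                  seed = derive_seed(seed, 40L + nchar(site)))
    cat(sprintf("%s %s: RMS-CV %.2f%% (95%% upper bound %.2f%%), %d cases\n",
                site, mode, r$rms_cv_percent, r$ci95_upper_percent,
                r$n_cases))
    out[[paste(site, mode, sep = "_")]] <-
      list(mode = mode, site = site, m = r$m, k = r$k,
           n_cases = r$n_cases,
           rms_cv_percent = r$rms_cv_percent,
           ci95_upper_percent = r$ci95_upper_percent, seed = seed)
  }
}
write_json(out, "results/precision.json", auto_unbox = TRUE, digits = NA)
cat("precision summary written to results/precision.json\n")
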