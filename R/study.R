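#' Run the full synthetic fracture-prediction study
#'
#' End-to-end composition at study scale: generate a cohort, build the
#' stratified reference database for the strata present, score every
#' patient's simulated RF scan through the FS pipeline, and evaluate FS
#' against both T-score markers, including paired DeLong comparisons and
#' (optionally) age- and BMI-adjusted ROC analyses.
#'
#' @param n Cohort size (default 1804, the size of a completed lumbar
#'   follow-up cohort).
#' @param site `"lumbar"` or `"femur"`.
#' @param seed Integer seed driving every random stage.
#' @param n_per_category Reference-database category size (default 100).
#' @param adjusted Also compute age/BMI-adjusted reports (default TRUE).
#' @param acq Optional acquisition override.
#' @return List: `cohort` (with `fs` column), `reports` (named list of
#'   `diagnostic_report`s for fs, rems_tscore, dxa_tscore and their
#'   adjusted versions), `delong` (FS vs each T-score, plus adjusted),
#'   `incidence_percent`.
#' @export
run_study <- function(n = 1804, site = c("lumbar", "femur"), seed = 1L,
                      n_per_category = 100L, adjusted = TRUE, acq = NULL) {
  site <- match.arg(site)
  cohort <- generate_cohort(n, site = site, seed = derive_seed(seed, 1L))
  db <- build_reference_database(cohort_strata(cohort),
                                 n_per_category = n_per_category,
                                 seed = derive_seed(seed, 2L), acq = acq)
  cohort <- score_cohort(cohort, db, seed = derive_seed(seed, 3L), acq = acq)

  reports <- list(
    fs = evaluate_marker(cohort, "fs"),
    rems_tscore = evaluate_marker(cohort, "rems_tscore",
                                  direction = "lower_is_positive",
                                  fixed_cutoff = -2.5),
    dxa_tscore = evaluate_marker(cohort, "dxa_tscore",
                                 direction = "lower_is_positive",
                                 fixed_cutoff = -2.5))

  mk <- function(col, dir) marker_series(cohort[[col]], cohort$fractured, dir)
  delong <- list(
    fs_vs_rems = delong_compare(mk("fs", "higher_is_positive"),
                                mk("rems_tscore", "lower_is_positive")),
    fs_vs_dxa = delong_compare(mk("fs", "higher_is_positive"),
                               mk("dxa_tscore", "lower_is_positive")))

  if (adjusted) {
    covs <- c("age", "bmi")
    reports$fs_adj <- evaluate_marker(cohort, "fs", covariates = covs)
    reports$rems_tscore_adj <- evaluate_marker(cohort, "rems_tscore",
                                               direction = "lower_is_positive",
                                               covariates = covs)
    reports$dxa_tscore_adj <- evaluate_marker(cohort, "dxa_tscore",
                                              direction = "lower_is_positive",
                                              covariates = covs)
    adj <- function(col, dir)
      covariate_adjust(mk(col, dir), cohort[, covs])
    delong$fs_vs_rems_adj <- delong_compare(adj("fs", "higher_is_positive"),
                                            adj("rems_tscore", "lower_is_positive"))
    delong$fs_vs_dxa_adj <- delong_compare(adj("fs", "higher_is_positive"),
                                           adj("dxa_tscore", "lower_is_positive"))
  }

  list(cohort = cohort, reports = reports, delong = delong,
       incidence_percent = 100 * mean(cohort$fractured),
       site = site, seed = seed)
}

#' FS mixture-recovery experiment
#'
#' Scores noise-free scans of patients with known latent fragility over a
#' grid of f values and reports the mean measured FS per f, the recovery
#' slope of FS/100 against f, and the largest absolute deviation of mean
#' FS from 100 f.
#'
#' @param f_grid Latent fragility values to probe.
#' @param n_patients Patients per grid point.
#' @param n_lines Scan lines (default 500 for tight binomial error).
#' @param seed Integer seed.
#' @param templates [spectral_templates()].
#' @return List: `f`, `mean_fs`, `slope`, `max_abs_error`.
#' @export
fs_recovery_experiment <- function(f_grid = c(0, 0.25, 0.5, 0.75, 1),
                                   n_patients = 8L, n_lines = 500L,
                                   seed = 1L,
                                   templates = spectral_templates()) {
  acq <- acquisition_params("lumbar", n_lines = n_lines, noise_sd = 0)
  strata <- data.frame(sex = "F", age_bin = "60-64", bmi_class = "normal",
                       site = "lumbar", stringsAsFactors = FALSE)
  db <- build_reference_database(strata, n_per_category = 20L,
                                 seed = derive_seed(seed, 1L),
                                 templates = templates, acq = acq)
  prof <- list(id = "rec", sex = "F", age = 62, bmi = 24)
  mean_fs <- vapply(seq_along(f_grid), function(i) {
    prof$f_latent <- f_grid[i]
    mean(vapply(seq_len(n_patients), function(j) {
      sc <- .synthesize_scan(f_grid[i], acq, templates,
                             tissue_seed = derive_seed(seed, 100L * i + j))
      score_patient(sc, prof, db)$fs
    }, numeric(1)))
  }, numeric(1))
  slope <- unname(stats::coef(stats::lm(mean_fs / 100 ~ f_grid))[2])
  list(f = f_grid, mean_fs = mean_fs, slope = slope,
       max_abs_error = max(abs(mean_fs - 100 * f_grid)))
}
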