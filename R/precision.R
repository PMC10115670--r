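## Short-term precision of FS, ISCD-style: root-mean-square coefficient of
## variation over repeated scans.

#' Root-mean-square coefficient of variation of a repeat study
#'
#' Per patient, CV_i = 100 sd_i / mean_i (sample SD, k - 1 denominator);
#' the study RMS-CV is the square root of the mean squared CV over
#' patients. "At 95% confidence level" is reported as the one-sided upper
#' confidence bound from the chi-square distribution of the pooled relative
#' variance with m (k - 1) degrees of freedom, the densitometric
#' precision-calculator convention. Both the point value and the bound are
#' returned.
#'
#' @param measurements Matrix, m patients x k repeats of non-negative
#'   measurements (FS percent in practice), no missing cells. The CV is
#'   unitless, so rescaling all measurements leaves the result unchanged.
#' @param site Optional site tag carried through to the output.
#' @return List: `rms_cv_percent`, `ci95_upper_percent`, `per_patient_cv`,
#'   `m`, `k`.
#' @export
rms_cv <- function(measurements, site = NULL) {
  x <- as.matrix(measurements)
  stopifnot(is.numeric(x), !anyNA(x), all(x >= 0))
  m <- nrow(x); k <- ncol(x)
  if (k < 2) stop("need at least 2 repeats per patient")
  mu <- rowMeans(x)
  if (any(mu <= 0)) stop("zero patient mean: CV undefined")
  sdv <- apply(x, 1, stats::sd)
  cv <- 100 * sdv / mu
  rms <- sqrt(mean(cv^2))
  df <- m * (k - 1)
  ci95 <- rms * sqrt(df / stats::qchisq(0.05, df))
  list(rms_cv_percent = rms, ci95_upper_percent = ci95,
       per_patient_cv = cv, m = m, k = k, site = site)
}

#' Run a simulated repeatability experiment
#'
#' Draws `m` patients (default 15, 9 women and 6 men, scanned `k` = 3 times
#' each, i.e. 45 scored cases per site as in the clinical precision
#' design), simulates repeated scans, scores each repeat through the full
#' FS pipeline and summarises with [rms_cv()]. In `"intra"` mode one
#' operator performs all repeats; in `"inter"` mode the repeats rotate over
#' three operators, whose operator-level speckle offsets add a variance
#' component, so the inter-operator RMS-CV exceeds the intra-operator one
#' in expectation.
#'
#' @param site `"lumbar"` or `"femur"`.
#' @param mode `"intra"` or `"inter"`.
#' @param m Number of patients (>= 2).
#' @param k Repeats per patient.
#' @param perturbation_sd,operator_sd See [simulate_repeat_scans()].
#' @param n_per_category Reference-database category size.
#' @param acq,templates,settings Pipeline configuration.
#' @param db Optional pre-built `reference_db`; built from the patients'
#'   strata when NULL.
#' @param patients Optional data.frame of patient profiles (id, sex, age,
#'   bmi, f_latent); drawn from [generate_cohort()] when NULL.
#' @param seed Integer seed.
#' @return The [rms_cv()] summary plus the `measurements` matrix and study
#'   metadata.
#' @export
run_precision_experiment <- function(site = c("lumbar", "femur"),
                                     mode = c("intra", "inter"),
                                     m = 15L, k = 3L,
                                     perturbation_sd = 0.15,
                                     operator_sd = 0.25,
                                     n_per_category = 100L,
                                     acq = NULL,
                                     templates = spectral_templates(),
                                     settings = fs_settings(),
                                     db = NULL, patients = NULL, seed = 1L) {
  site <- match.arg(site)
  mode <- match.arg(mode)
  if (m < 2) stop("m must be >= 2")
  acq_s <- if (is.null(acq)) acquisition_params(site) else acq
  if (is.null(patients)) {
    cohort <- generate_cohort(max(m, 15L), sex_fraction_female = 0.6,
                              site = site, seed = derive_seed(seed, 77L))
    patients <- cohort[seq_len(m), ]
  } else {
    stopifnot(nrow(patients) >= m)
    patients <- patients[seq_len(m), ]
    patients$site <- site
  }
  if (is.null(db))
    db <- build_reference_database(cohort_strata(patients),
                                   n_per_category = n_per_category,
                                   seed = derive_seed(seed, 88L),
                                   templates = templates,
                                   settings = settings, acq = acq_s)
  operator_ids <- if (mode == "inter") {
    rep_len(c("experienced", "trainee1", "trainee2"), k)
  } else rep("experienced", k)

  meas <- matrix(NA_real_, nrow = m, ncol = k)
  for (i in seq_len(m)) {
    p <- patients[i, ]
    scans <- simulate_repeat_scans(p, acq_s, k, operator_ids = operator_ids,
                                   perturbation_sd = perturbation_sd,
                                   operator_sd = operator_sd,
                                   templates = templates,
                                   seed = derive_seed(seed, i))
    meas[i, ] <- vapply(scans, function(sc)
      score_patient(sc, p, db, settings)$fs, numeric(1))
  }
  # FS can legitimately be 0 for a very low-fragility patient; CV needs a
  # positive mean, so shift-free scoring keeps patients with mean > 0 only.
  keep <- rowMeans(meas) > 0
  out <- rms_cv(meas[keep, , drop = FALSE], site = site)
  out$mode <- mode
  out$measurements <- meas
  out$n_cases <- m * k
  out$operator_ids <- operator_ids
  out
}
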