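#' Default effect parameters for the cohort generator
#'
#' Returns the generator settings that define the simulated study conditions:
#' the latent-fragility model, the fracture link and the T-score model.
#'
#' The latent fragility `f` in \[0, 1] of subject i is
#' `f_i = plogis(a0_sex + a1 * (age_i - 60)/10 + e_i)`, `e_i ~ N(0, f_sd)`,
#' so fragility increases monotonically with age on average. Incident
#' fracture is Bernoulli with
#' `p_i = plogis(alpha + beta_f * f_i + gamma_age * (age_i - 60))`.
#' DXA and REMS T-scores are two noisy readouts of one bone-mineral-density
#' latent that is only partially correlated (`bmd_f_cor`) with the driver of
#' `f`, so the fragility signal is not reducible to BMD.
#'
#' `alpha` is calibrated per site so that default cohorts reproduce observed
#' incident-fracture frequencies of roughly 13.7% (lumbar, any major
#' osteoporotic fracture) and 2.9% (femur, hip fracture).
#'
#' @param site `"lumbar"` or `"femur"`.
#' @return Named list of generator settings.
#' @export
cohort_effects <- function(site = c("lumbar", "femur")) {
  site <- match.arg(site)
  list(
    f_intercept   = c(F = -0.80, M = -1.15),
    f_age_slope   = 0.50,   # logit units per decade of age
    f_sd          = 0.80,   # subject-level noise on the logit of f
    beta_f        = 4.00,   # fracture log-odds per unit f
    gamma_age     = 0.06,   # fracture log-odds per year of age
    alpha         = if (site == "lumbar") -3.59 else -5.47,
    bmd_f_cor     = 0.45,   # correlation of the BMD latent with the f driver
    tscore_mean   = c(F = -2.1, M = -0.9),
    tscore_sd     = 1.3,
    tscore_noise_sd = 0.35  # device-specific measurement noise (SD units)
  )
}

#' Generate a synthetic fracture-risk cohort
#'
#' Draws a cohort of patient profiles with anthropometric covariates, a
#' latent fragility `f` in \[0, 1], DXA and REMS T-scores, and a 5-year
#' incident-fracture outcome, with the dependence structure described in
#' [cohort_effects()]. Ages are restricted to the 30--90 year eligibility
#' window. Lumbar cohorts carry major osteoporotic fracture outcomes,
#' femoral cohorts hip fractures only.
#'
#' @param n Number of patients (>= 2).
#' @param sex_fraction_female Proportion of women in \[0, 1] (default 0.715).
#' @param site `"lumbar"` or `"femur"`.
#' @param effect_params Generator settings, see [cohort_effects()].
#' @param seed Integer RNG seed; the output is a pure function of the
#'   arguments and this seed.
#' @return A `data.frame` with columns id, sex, age, height_cm, weight_kg,
#'   bmi, site, f_latent, dxa_tscore, rems_tscore, fractured, fracture_type,
#'   time_to_event_y.
#' @export
generate_cohort <- function(n, sex_fraction_female = 0.715,
                            site = c("lumbar", "femur"),
                            effect_params = cohort_effects(site),
                            seed = 1L) {
  site <- match.arg(site)
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    stop("n must be an integer >= 2")
  if (sex_fraction_female < 0 || sex_fraction_female > 1)
    stop("sex_fraction_female must be in [0, 1]")
  ep <- effect_params
  set.seed(seed)

  n <- as.integer(n)
  sex <- ifelse(runif(n) < sex_fraction_female, "F", "M")
  female <- sex == "F"

  # Age: women concentrated around 60, men more dispersed; truncated to the
  # 30-90 eligibility window by redrawing.
  rtrunc_norm <- function(m, mu, sd, lo, hi) {
    x <- rnorm(m, mu, sd)
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
      x[bad] <- rnorm(length(bad), mu, sd)
      bad <- bad[x[bad] < lo | x[bad] > hi]
    }
    x
  }
  age <- numeric(n)
  age[female]  <- rtrunc_norm(sum(female), 60, 9, 30, 90)
  age[!female] <- rtrunc_norm(sum(!female), 61, 15, 30, 90)

  height <- ifelse(female, rnorm(n, 160, 7.4), rnorm(n, 172.5, 7.9))
  weight <- ifelse(female, rnorm(n, 63.5, 9.6), rnorm(n, 77, 11))
  weight <- pmax(weight, 35)
  height <- pmax(height, 130)
  bmi <- weight / (height / 100)^2

  # Latent fragility.
  a0 <- ep$f_intercept[sex]
  eta_f <- a0 + ep$f_age_slope * (age - 60) / 10 + rnorm(n, 0, ep$f_sd)
  f <- plogis(eta_f)

  # BMD latent, partially correlated with the standardized f driver.
  z_f <- (eta_f - mean(eta_f)) / stats::sd(eta_f)
  bmd <- -ep$bmd_f_cor * z_f + sqrt(1 - ep$bmd_f_cor^2) * rnorm(n)
  mu_t <- ep$tscore_mean[sex]
  dxa_t  <- mu_t + ep$tscore_sd * bmd + rnorm(n, 0, ep$tscore_noise_sd)
  rems_t <- mu_t + ep$tscore_sd * bmd + rnorm(n, 0, ep$tscore_noise_sd)

  # Incident fracture over follow-up.
  p_frac <- plogis(ep$alpha + ep$beta_f * f + ep$gamma_age * (age - 60))
  fractured <- runif(n) < p_frac
  follow_up <- runif(n, 2, 5)
  tte <- ifelse(fractured, runif(n) * follow_up, follow_up)
  ftype <- ifelse(fractured,
                  if (site == "lumbar") "major_osteoporotic" else "hip",
                  "none")

  data.frame(
    id = sprintf("P%05d", seq_len(n)),
    sex = sex,
    age = age,
    height_cm = height,
    weight_kg = weight,
    bmi = bmi,
    site = site,
    f_latent = f,
    dxa_tscore = unname(dxa_t),
    rems_tscore = unname(rems_t),
    fractured = fractured,
    fracture_type = ftype,
    time_to_event_y = tte,
    stringsAsFactors = FALSE
  )
}
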