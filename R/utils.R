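#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive a child RNG seed
#'
#' Maps a base seed and an index to a new seed in the 32-bit integer range,
#' so that independent stages of a workflow can be driven from one seed.
#'
#' @param seed Base integer seed.
#' @param index Integer stage index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483629L)
}

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

hann_window <- function(n) {
  stopifnot(n >= 2)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

#' Round half away from zero
#'
#' Presentation rounding for percentages and ratios (base `round()` rounds
#' half to even, which turns e.g. 6.25 into 6.2 rather than 6.3).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Five-year age bin label
#'
#' Reference populations are stratified into 5-year age intervals spanning
#' 30--90 years; age 90 is folded into the last bin.
#'
#' @param age Numeric age(s) in years, in \[30, 90].
#' @return Character label(s) such as `"60-64"`.
#' @export
age_bin <- function(age) {
  stopifnot(all(is.finite(age)), all(age >= 30), all(age <= 90))
  lo <- pmin(30 + 5 * floor((age - 30) / 5), 85)
  sprintf("%d-%d", as.integer(lo), as.integer(lo + 4))
}

#' WHO body-mass-index class
#'
#' Classes: underweight (< 18.5), normal (18.5--25), overweight (25--30),
#' obese (>= 30 kg/m^2).
#'
#' @param bmi Numeric BMI value(s) in kg/m^2.
#' @return Character label(s) in `c("under", "normal", "over", "obese")`.
#' @export
bmi_class <- function(bmi) {
  stopifnot(all(is.finite(bmi)), all(bmi > 0))
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf),
      labels = c("under", "normal", "over", "obese"), right = FALSE) |>
    as.character()
}

#' Reference-database stratum key
#'
#' Builds the exact lookup key used by the reference database:
#' sex, 5-year age bin, BMI class and anatomical site.
#'
#' @param sex `"F"` or `"M"`.
#' @param age Age in years.
#' @param bmi BMI in kg/m^2.
#' @param site `"lumbar"` or `"femur"`.
#' @return Character key, e.g. `"F_60-64_normal_lumbar"`.
#' @export
stratum_key <- function(sex, age, bmi, site) {
  stopifnot(all(sex %in% c("F", "M")), all(site %in% c("lumbar", "femur")))
  paste(sex, age_bin(age), bmi_class(bmi), site, sep = "_")
}
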