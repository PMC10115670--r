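#' Spectral templates for frail and non-frail bone backscatter
#'
#' Phenomenological magnitude-spectrum templates used by the RF generator.
#' The non-frail template is a Gaussian band centred on the probe's nominal
#' frequency; the frail template is down-shifted in centre frequency with a
#' steeper high-frequency roll-off, a proxy for the altered trabecular
#' micro-architecture of fragile bone. Both are unit-normalised when sampled
#' on a frequency grid.
#'
#' The `"orthogonal"` pair has disjoint supports (non-overlapping bands);
#' with it, a segment synthesised from one template can never correlate
#' better with the other, which gives exact mixture recovery in noise-free
#' tests.
#'
#' @param kind `"default"` (overlapping, realistic) or `"orthogonal"`
#'   (disjoint supports, used for exact-recovery checks).
#' @param center_frequency Nominal probe frequency in MHz (default 3.5).
#' @return A list with functions `frail(f)` and `nonfrail(f)` mapping a
#'   frequency grid in MHz to non-negative magnitudes, plus the `kind`.
#' @export
spectral_templates <- function(kind = c("default", "orthogonal"),
                               center_frequency = 3.5) {
  kind <- match.arg(kind)
  fc <- center_frequency
  if (kind == "default") {
    # Asymmetric Gaussians: sd below / above the centre differ so the frail
    # spectrum rolls off faster at high frequency.
    nonfrail <- function(f) {
      s <- ifelse(f < fc, 0.80, 0.80)
      exp(-(f - fc)^2 / (2 * s^2))
    }
    frail <- function(f) {
      c0 <- fc - 0.8
      s <- ifelse(f < c0, 0.80, 0.45)
      exp(-(f - c0)^2 / (2 * s^2))
    }
  } else {
    # Rectangular, disjoint bands.
    nonfrail <- function(f) as.numeric(f >= fc + 0.25 & f <= fc + 1.75)
    frail    <- function(f) as.numeric(f >= fc - 1.75 & f <= fc - 0.25)
  }
  structure(list(frail = frail, nonfrail = nonfrail, kind = kind,
                 center_frequency = fc),
            class = "rf_templates")
}
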