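## RF scan synthesis: phenomenological two-template spectral mixture with a
## specular bone-interface echo. No wave-propagation physics.

# Length (samples) of the backscatter block placed below the interface; the
# FS analysis window must fall inside it.
.BACKSCATTER_LEN <- 192L
.BACKSCATTER_GAP <- 4L    # samples between interface echo centre and block
.ECHO_AMPLITUDE  <- 8     # interface echo amplitude relative to unit speckle
.ECHO_WIDTH      <- 4     # Gaussian envelope SD of the echo, samples

#' Acquisition parameters for a simulated REMS scan
#'
#' Defaults follow the clinical acquisition geometry: a convex probe at a
#' nominal 3.5 MHz centre frequency, lumbar scans covering four vertebrae
#' (L1--L4, 80 s) and femoral scans a single femoral-neck ROI (40 s). The
#' sampling rate must satisfy Nyquist with margin for the analysis band.
#' At 16 MHz sampling, one sample spans c/(2 fs) = 48.1 um of depth, so a
#' 1024-sample line images about 4.9 cm and an interface placed no deeper
#' than sample 400 keeps at least 3 cm of image below the bone surface.
#'
#' @param site `"lumbar"` or `"femur"`.
#' @param center_frequency Probe nominal frequency, MHz.
#' @param sampling_rate RF sampling rate, MHz; must exceed twice the centre
#'   frequency.
#' @param n_lines Scan lines per scan (lumbar default 128 = 32 per vertebra;
#'   femur default 64).
#' @param samples_per_line Depth samples per RF line.
#' @param noise_sd Additive white-noise SD relative to unit speckle
#'   amplitude.
#' @return An `acquisition_params` list, validated.
#' @export
acquisition_params <- function(site = c("lumbar", "femur"),
                               center_frequency = 3.5,
                               sampling_rate = 16,
                               n_lines = if (site[1] == "lumbar") 128L else 64L,
                               samples_per_line = 1024L,
                               noise_sd = 0.3) {
  site <- match.arg(site)
  if (sampling_rate <= 2 * center_frequency)
    stop("Nyquist violation: sampling_rate must exceed 2 x center_frequency")
  n_lines <- as.integer(n_lines)
  n_rois <- if (site == "lumbar") 4L else 1L
  if (n_lines < 8 || n_lines %% n_rois != 0)
    stop("n_lines must be >= 8 and divisible by the number of ROIs")
  samples_per_line <- as.integer(samples_per_line)
  if (samples_per_line < 512)
    stop("samples_per_line must be >= 512")
  structure(list(
    site = site,
    center_frequency = center_frequency,
    sampling_rate = sampling_rate,
    n_lines = n_lines,
    samples_per_line = samples_per_line,
    scan_duration = if (site == "lumbar") 80 else 40,
    n_rois = n_rois,
    noise_sd = noise_sd
  ), class = "acquisition_params")
}

# ROI labels per line: 4 contiguous vertebral blocks for lumbar, one
# femoral-neck block for femur.
.roi_partition <- function(acq) {
  if (acq$site == "lumbar") {
    rep(c("L1", "L2", "L3", "L4"), each = acq$n_lines / 4L)
  } else {
    rep("neck", acq$n_lines)
  }
}

# Template magnitude on the full FFT grid of length n (frequencies folded at
# Nyquist so the synthesised time series has a symmetric power spectrum).
.template_on_grid <- function(template_fun, n, sampling_rate) {
  f <- (0:(n - 1)) * sampling_rate / n
  f <- pmin(f, sampling_rate - f)
  m <- template_fun(f)
  if (!all(is.finite(m)) || any(m < 0)) stop("invalid template magnitudes")
  if (sum(m) <= 0) stop("empty template")
  m
}

# Complex standard-normal matrix used as the speckle innovation; mixing two
# of these with weights (w1, w2), w1^2 + w2^2 = 1, again yields a standard
# speckle field.
.speckle_innovation <- function(n, n_lines, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * n_lines), imaginary = rnorm(n * n_lines)),
         nrow = n, ncol = n_lines)
}

# Colored speckle: shape innovations by the per-line template magnitude and
# invert; columns are normalised to unit variance deterministically.
.colored_speckle <- function(Z, M_frail, M_nonfrail, frail_line) {
  n <- nrow(Z)
  Mmat <- matrix(M_nonfrail, nrow = n, ncol = ncol(Z))
  if (any(frail_line)) Mmat[, frail_line] <- M_frail
  Y <- Re(stats::mvfft(Mmat * Z, inverse = TRUE)) / n
  scale <- n / sqrt(colSums(Mmat^2))
  sweep(Y, 2, scale, `*`)
}

# Core synthesiser. The bone/tissue realisation (interface depth, per-line
# template choice, speckle innovation) is a pure function of `tissue_seed`;
# repeated scans of the same patient reuse it and perturb around it.
.synthesize_scan <- function(f, acq, templates, tissue_seed,
                             extra_weights = numeric(0),
                             extra_seeds = integer(0),
                             depth_shift = 0L,
                             noise_seed = tissue_seed + 1L,
                             id = "scan") {
  stopifnot(f >= 0, f <= 1, length(extra_weights) == length(extra_seeds))
  if (sum(extra_weights^2) > 1) stop("speckle mixing weights exceed unity")
  S <- acq$samples_per_line
  L <- acq$n_lines
  nb <- .BACKSCATTER_LEN

  M_frail <- .template_on_grid(templates$frail, nb, acq$sampling_rate)
  M_nonfrail <- .template_on_grid(templates$nonfrail, nb, acq$sampling_rate)

  # Patient tissue realisation.
  set.seed(tissue_seed)
  # keep >= 3 cm of image below the interface: deepest allowed index leaves
  # 624 samples (~3 cm at 16 MHz) to the image bottom
  d_max <- S - 624L
  d0 <- sample(280L:max(300L, d_max), 1L)
  frail_line <- runif(L) < f
  Z <- matrix(complex(real = rnorm(nb * L), imaginary = rnorm(nb * L)),
              nrow = nb, ncol = L)

  w0 <- sqrt(1 - sum(extra_weights^2))
  if (length(extra_weights)) {
    Z <- w0 * Z
    for (i in seq_along(extra_weights)) {
      if (extra_weights[i] != 0)
        Z <- Z + extra_weights[i] *
          .speckle_innovation(nb, L, extra_seeds[i])
    }
  }
  speckle <- .colored_speckle(Z, M_frail, M_nonfrail, frail_line)

  d <- max(200L, min(as.integer(d0 + depth_shift), S - 624L))
  rf <- matrix(0, nrow = S, ncol = L)
  # Specular interface echo: Gaussian-windowed tone burst centred at depth d.
  t_all <- seq_len(S)
  pulse <- .ECHO_AMPLITUDE * exp(-(t_all - d)^2 / (2 * .ECHO_WIDTH^2)) *
    cos(2 * pi * acq$center_frequency / acq$sampling_rate * (t_all - d))
  rf <- rf + pulse   # same interface depth on every line
  rows <- (d + .BACKSCATTER_GAP):(d + .BACKSCATTER_GAP + nb - 1L)
  rf[rows, ] <- rf[rows, ] + speckle
  if (acq$noise_sd > 0) {
    set.seed(noise_seed)
    rf <- rf + acq$noise_sd * rnorm(S * L)
  }

  structure(list(
    rf = t(rf),                          # n_lines x samples
    sampling_rate = acq$sampling_rate,
    center_frequency = acq$center_frequency,
    site = acq$site,
    roi_partition = .roi_partition(acq),
    interface_depth_truth = d,
    template_choice_truth = frail_line,
    f_truth = f,
    id = id
  ), class = "rf_scan")
}

#' Simulate one RF scan for a patient
#'
#' Synthesises an RF scan as a two-template spectral mixture: each scan
#' line's sub-surface backscatter segment is drawn from the frail template
#' with probability equal to the patient's latent fragility `f` and from the
#' non-frail template otherwise, independently per line, band-limited around
#' the probe centre frequency, plus additive white noise. A bright specular
#' interface echo is placed at a known depth (stored as ground truth in
#' `interface_depth_truth`) with at least 3 cm of image depth below it.
#'
#' @param profile A list or one-row data.frame with at least `f_latent` (or
#'   `f`) and optionally `id`.
#' @param acq [acquisition_params()].
#' @param templates [spectral_templates()].
#' @param seed Integer seed; output is a pure function of arguments + seed.
#' @return An `rf_scan`: list with `rf` (n_lines x samples matrix),
#'   acquisition attributes, ROI partition, and generator ground truth.
#' @export
simulate_rf_scan <- function(profile, acq, templates = spectral_templates(),
                             seed = 1L) {
  f <- if (!is.null(profile$f_latent)) profile$f_latent else profile$f
  if (is.null(f)) stop("profile must carry f_latent (or f)")
  id <- if (!is.null(profile$id)) as.character(profile$id) else "scan"
  .synthesize_scan(as.numeric(f), acq, templates, tissue_seed = as.integer(seed),
                   id = id)
}

#' Generate a labelled reference population of RF scans
#'
#' Populates every requested stratum (sex, 5-year age bin, BMI class, site)
#' with `n_per_category` scans, split evenly between "fractured" subjects
#' (synthesised at f = 1, pure frail-template backscatter) and
#' "non-fractured" subjects (f = 0). The default category size of 100
#' mirrors the construction of the clinical reference database.
#'
#' @param strata A data.frame with columns sex, age_bin, bmi_class, site, or
#'   a list of such records.
#' @param n_per_category Even count >= 2 per stratum (default 100).
#' @param seed Integer seed.
#' @param acq Optional [acquisition_params()] override; by default derived
#'   from each stratum's site.
#' @param templates [spectral_templates()].
#' @return A list of `rf_scan` objects, each carrying `label`
#'   ("fractured"/"non-fractured") and `stratum` fields.
#' @export
generate_reference_population <- function(strata, n_per_category = 100L,
                                          seed = 1L, acq = NULL,
                                          templates = spectral_templates()) {
  strata <- .as_strata_df(strata)
  if (nrow(strata) == 0) stop("empty strata list")
  if (n_per_category < 2 || n_per_category %% 2 != 0)
    stop("n_per_category must be an even count >= 2")
  out <- vector("list", nrow(strata) * n_per_category)
  idx <- 1L
  for (s in seq_len(nrow(strata))) {
    acq_s <- if (is.null(acq)) acquisition_params(strata$site[s]) else acq
    half <- n_per_category / 2L
    for (j in seq_len(n_per_category)) {
      lab <- if (j <= half) "fractured" else "non-fractured"
      f <- if (lab == "fractured") 1 else 0
      sc <- .synthesize_scan(f, acq_s, templates,
                             tissue_seed = derive_seed(seed, (s - 1L) * n_per_category + j),
                             id = sprintf("ref_%s_%03d", .stratum_label(strata[s, ]), j))
      sc$label <- lab
      sc$stratum <- .stratum_label(strata[s, ])
      out[[idx]] <- sc
      idx <- idx + 1L
    }
  }
  out
}

.as_strata_df <- function(strata) {
  if (is.data.frame(strata)) {
    stopifnot(all(c("sex", "age_bin", "bmi_class", "site") %in% names(strata)))
    return(strata)
  }
  do.call(rbind, lapply(strata, function(s)
    data.frame(sex = s$sex, age_bin = s$age_bin, bmi_class = s$bmi_class,
               site = s$site, stringsAsFactors = FALSE)))
}

.stratum_label <- function(row) {
  paste(row$sex, row$age_bin, row$bmi_class, row$site, sep = "_")
}

#' Simulate repeated scans of one patient (precision study design)
#'
#' All repeats share the patient's latent fragility, per-line template
#' realisation and baseline speckle (the bone does not change between
#' scans). Each repeat perturbs the probe position (interface-depth jitter)
#' and partially re-realises the speckle with weight `perturbation_sd`;
#' additive acquisition noise is redrawn per repeat. When several distinct
#' `operator_ids` are supplied, each operator contributes an
#' operator-specific speckle component of weight `operator_sd`
#' (probe-handling differences); with a single operator, or with
#' `operator_sd = 0`, the design reduces to the intra-operator case.
#'
#' @param profile Patient profile (needs `f_latent` or `f`).
#' @param acq [acquisition_params()].
#' @param k Number of repeats, >= 2.
#' @param operator_ids Optional character vector of length `k`.
#' @param perturbation_sd Relative repeat-level perturbation in \[0, 1).
#' @param operator_sd Relative operator-level offset in \[0, 1).
#' @param templates [spectral_templates()].
#' @param seed Integer seed.
#' @return List of `k` `rf_scan` objects.
#' @export
simulate_repeat_scans <- function(profile, acq, k, operator_ids = NULL,
                                  perturbation_sd = 0.15, operator_sd = 0.25,
                                  templates = spectral_templates(), seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  f <- if (!is.null(profile$f_latent)) profile$f_latent else profile$f
  if (is.null(f)) stop("profile must carry f_latent (or f)")
  if (is.null(operator_ids)) operator_ids <- rep("op1", k)
  stopifnot(length(operator_ids) == k)
  ops <- unique(operator_ids)
  op_seed <- vapply(seq_along(ops),
                    function(i) derive_seed(seed, 500000L + i), integer(1))
  names(op_seed) <- ops

  tissue_seed <- derive_seed(seed, 0L)
  set.seed(derive_seed(seed, 1L))
  depth_jitter <- round(rnorm(k, 0, perturbation_sd * 20))

  lapply(seq_len(k), function(j) {
    w <- c(perturbation_sd,
           if (length(ops) > 1 || operator_sd > 0) operator_sd else numeric(0))
    sds <- c(derive_seed(seed, 1000L + j),
             if (length(w) > 1) op_seed[[operator_ids[j]]] else integer(0))
    keep <- w > 0
    sc <- .synthesize_scan(f, acq, templates, tissue_seed = tissue_seed,
                           extra_weights = w[keep],
                           extra_seeds = as.integer(sds[keep]),
                           depth_shift = as.integer(depth_jitter[j]),
                           noise_seed = derive_seed(seed, 2000L + j),
                           id = sprintf("%s_rep%d",
                                        if (!is.null(profile$id)) profile$id else "patient",
                                        j))
    sc$operator <- operator_ids[j]
    sc$repeat_index <- j
    sc
  })
}
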