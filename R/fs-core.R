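## Fragility Score pipeline: envelope -> interface segmentation -> ROI
## selection -> per-segment spectra -> correlation classification against
## stratum-matched reference models -> aggregation.

#' Default FS analysis settings
#'
#' @param center_frequency Probe nominal frequency, MHz.
#' @return List with the ROI window geometry (samples), segmentation margin,
#'   confidence threshold, and the spectral analysis band
#'   \[fc/2, 2 fc] MHz.
#' @export
fs_settings <- function(center_frequency = 3.5) {
  list(
    window_len = 128L,        # RF segment length below the interface
    offset = 8L,              # samples between interface and window start
    min_depth_margin = 100L,  # ignore near-field when searching the interface
    min_confidence = 3,       # peak / line-median acceptance threshold
    band = c(center_frequency / 2, 2 * center_frequency)  # MHz
  )
}

#' Envelope (B-mode proxy) of an RF scan
#'
#' Per-line magnitude of the analytic signal, computed by FFT half-spectrum
#' doubling, then log-compressed with `log1p` (monotone, zero maps to zero).
#'
#' @param scan An `rf_scan`.
#' @return Matrix of the same shape as `scan$rf` with non-negative values.
#' @export
envelope_image <- function(scan) {
  rf <- scan$rf
  stopifnot(is.matrix(rf), all(is.finite(rf)))
  if (all(rf == 0)) stop("empty signal")
  n <- ncol(rf)
  X <- stats::mvfft(t(rf))          # samples x lines
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::mvfft(X * h, inverse = TRUE) / n
  t(log1p(Mod(z)))
}

#' Segment the bone interface from an envelope image
#'
#' Per line, the interface is the strongest envelope peak deeper than
#' `min_depth_margin`; its confidence is the peak amplitude relative to the
#' line median. A line fails when no sample exceeds 3x the line median; if
#' more than half the lines fail, no interface exists in the image. The
#' accepted trace is smoothed with a running median of width 5 lines.
#'
#' @param image Envelope matrix from [envelope_image()] (n_lines x samples).
#' @param min_depth_margin Samples to skip at the top of each line.
#' @return An `interface_trace`: list with integer `depth_index` (0-based)
#'   and numeric `confidence`, one per line.
#' @export
segment_bone_interface <- function(image, min_depth_margin = 100L) {
  stopifnot(is.matrix(image))
  S <- ncol(image)
  if (min_depth_margin >= S - 1) stop("depth margin exceeds line length")
  sub <- image[, (min_depth_margin + 1L):S, drop = FALSE]
  peak_rel <- max.col(sub, ties.method = "first")
  peak_val <- sub[cbind(seq_len(nrow(sub)), peak_rel)]
  med <- apply(image, 1, stats::median)
  conf <- ifelse(med > 0, peak_val / med, Inf)
  if (mean(peak_val > 3 * med) <= 0.5) stop("no interface found")
  depth <- peak_rel + min_depth_margin - 1L   # 0-based sample index
  if (length(depth) >= 5) depth <- as.integer(stats::runmed(depth, 5))
  structure(list(depth_index = depth, confidence = conf),
            class = "interface_trace")
}

#' Select per-line RF segments below the interface
#'
#' One segment per accepted scan line: the half-open sample window
#' `[depth + offset, depth + offset + window_len)` strictly below the
#' interface. Lines whose segmentation confidence falls below
#' `min_confidence` are excluded. Each segment carries its line's ROI id.
#'
#' @param scan An `rf_scan`.
#' @param trace An `interface_trace` for the scan.
#' @param window_len Segment length in samples.
#' @param offset Samples between the interface and the window start.
#' @param min_confidence Minimum per-line confidence to keep the line.
#' @return List of `rf_segment`s: `line`, `roi`, `sample_window`
#'   (0-based, half-open), `samples`.
#' @export
select_roi <- function(scan, trace, window_len = 128L, offset = 8L,
                       min_confidence = 3) {
  S <- ncol(scan$rf)
  keep <- which(trace$confidence >= min_confidence)
  lapply(keep, function(i) {
    start <- trace$depth_index[i] + offset          # 0-based
    if (start + window_len > S)
      stop(sprintf("window [%d, %d) exceeds line length %d on line %d",
                   start, start + window_len, S, i))
    list(line = i,
         roi = scan$roi_partition[i],
         sample_window = c(start, start + window_len),
         samples = scan$rf[i, (start + 1L):(start + window_len)])
  })
}

#' Band-limited normalized power spectrum of an RF segment
#'
#' Hann-windowed periodogram, zero-padded to the next power of two at least
#' four times the segment length, restricted to the analysis band and
#' normalised to unit area (sum of magnitudes times bin width = 1).
#'
#' @param segment An `rf_segment` (or any list with `samples`), length >= 32.
#' @param sampling_rate Sampling rate in MHz.
#' @param band Two-element vector `c(f_lo, f_hi)` in MHz, inside Nyquist.
#' @return A `spectrum_fs`: list with `frequencies` (MHz) and `magnitude`.
#' @export
compute_spectrum <- function(segment, sampling_rate, band) {
  x <- if (is.list(segment)) segment$samples else segment
  n <- length(x)
  if (n < 32) stop("segment too short (need >= 32 samples)")
  if (band[1] < 0 || band[2] > sampling_rate / 2 || band[1] >= band[2])
    stop("band outside Nyquist range")
  xw <- x * hann_window(n)
  nfft <- next_pow2(4L * n)
  p <- Mod(stats::fft(c(xw, numeric(nfft - n))))^2
  freqs <- (0:(nfft - 1)) * sampling_rate / nfft
  sel <- which(freqs >= band[1] & freqs <= band[2])
  mag <- p[sel]
  df <- sampling_rate / nfft
  tot <- sum(mag) * df
  if (tot <= 0) stop("degenerate spectrum")
  structure(list(frequencies = freqs[sel], magnitude = mag / tot),
            class = "spectrum_fs")
}

#' Build a stratified reference database from labelled spectra
#'
#' For each stratum, the frail (non-frail) model is the per-bin mean of the
#' member spectra labelled "fractured" ("non-fractured"), re-normalised to
#' unit area; member counts are recorded. Every stratum must contribute at
#' least two spectra per label.
#'
#' @param spectra List of records, each with `stratum` (key string), `label`
#'   ("fractured"/"non-fractured") and `spectrum` (a `spectrum_fs`).
#' @return A `reference_db`: list with `strata`, a named list of model pairs
#'   `list(frail_model, nonfrail_model, n_frail, n_nonfrail)`.
#' @export
build_reference_models <- function(spectra) {
  stopifnot(length(spectra) > 0)
  keys <- vapply(spectra, function(r) r$stratum, character(1))
  labs <- vapply(spectra, function(r) r$label, character(1))
  strata <- list()
  for (k in unique(keys)) {
    sel_f <- which(keys == k & labs == "fractured")
    sel_n <- which(keys == k & labs == "non-fractured")
    if (length(sel_f) < 2 || length(sel_n) < 2)
      stop(sprintf("stratum %s lacks a label class (need >= 2 per label)", k))
    grid <- spectra[[sel_f[1]]]$spectrum$frequencies
    mk_model <- function(sel) {
      mags <- vapply(spectra[sel], function(r) {
        if (!isTRUE(all.equal(r$spectrum$frequencies, grid)))
          stop("frequency grid mismatch within stratum ", k)
        r$spectrum$magnitude
      }, numeric(length(grid)))
      m <- rowMeans(mags)
      df <- grid[2] - grid[1]
      structure(list(frequencies = grid, magnitude = m / (sum(m) * df)),
                class = "spectrum_fs")
    }
    strata[[k]] <- list(frail_model = mk_model(sel_f),
                        nonfrail_model = mk_model(sel_n),
                        n_frail = length(sel_f),
                        n_nonfrail = length(sel_n))
  }
  structure(list(strata = strata), class = "reference_db")
}

#' Classify one segment spectrum against a reference model pair
#'
#' Pearson correlation of the magnitude vector with each model; the segment
#' is "frail" iff its correlation with the frail model strictly exceeds the
#' correlation with the non-frail model (ties are resolved as non-frail, so
#' ambiguity never inflates fragility).
#'
#' @param s A `spectrum_fs`.
#' @param pair A model pair from a `reference_db` stratum.
#' @return List `label` ("frail"/"nonfrail"), `r_frail`, `r_nonfrail`.
#' @export
classify_segment <- function(s, pair) {
  if (!isTRUE(all.equal(s$frequencies, pair$frail_model$frequencies)))
    stop("frequency grid mismatch between spectrum and models")
  if (stats::sd(s$magnitude) == 0 ||
      stats::sd(pair$frail_model$magnitude) == 0 ||
      stats::sd(pair$nonfrail_model$magnitude) == 0)
    stop("zero-variance magnitude vector")
  r_f <- stats::cor(s$magnitude, pair$frail_model$magnitude)
  r_n <- stats::cor(s$magnitude, pair$nonfrail_model$magnitude)
  list(label = if (r_f > r_n) "frail" else "nonfrail",
       r_frail = r_f, r_nonfrail = r_n)
}

#' Aggregate per-segment labels into the Fragility Score
#'
#' Each ROI's value is the percentage of its RF segments classified as
#' frail; the patient-level FS is the unweighted mean of the ROI values,
#' regardless of how many segments each ROI contributed.
#'
#' @param labels_by_roi Named list mapping ROI id to a character vector of
#'   per-segment labels ("frail"/"nonfrail").
#' @param correlations Optional list of per-segment `(r_frail, r_nonfrail)`.
#' @return An `fs_result`: `fs` (percent in \[0, 100]), `per_roi`,
#'   `per_segment_labels`, `correlations`.
#' @export
fragility_score <- function(labels_by_roi, correlations = NULL) {
  if (length(labels_by_roi) < 1) stop("need at least one ROI")
  per_roi <- vapply(names(labels_by_roi), function(roi) {
    labs <- labels_by_roi[[roi]]
    if (length(labs) == 0) stop(sprintf("empty ROI: %s", roi))
    100 * mean(labs == "frail")
  }, numeric(1))
  structure(list(fs = mean(per_roi),
                 per_roi = per_roi,
                 per_segment_labels = unlist(labels_by_roi, use.names = FALSE),
                 correlations = correlations),
            class = "fs_result")
}

#' Score a patient: full FS pipeline
#'
#' Composes the five analysis steps on each scan: envelope detection, bone
#' interface segmentation, ROI segment selection, per-segment spectrum
#' estimation, correlation classification against the patient's
#' stratum-matched reference models, and ROI-mean aggregation. With several
#' scans, the patient FS is the mean of the per-scan FS values.
#'
#' @param scans An `rf_scan` or list of them.
#' @param profile Patient profile with `sex`, `age`, `bmi` (site is taken
#'   from the scan).
#' @param db A `reference_db` containing the patient's stratum.
#' @param settings [fs_settings()].
#' @return An `fs_result` (fields of the last scan's decomposition, `fs`
#'   averaged over scans).
#' @export
score_patient <- function(scans, profile, db, settings = fs_settings()) {
  if (inherits(scans, "rf_scan")) scans <- list(scans)
  key <- stratum_key(profile$sex, profile$age, profile$bmi, scans[[1]]$site)
  pair <- db$strata[[key]]
  if (is.null(pair))
    stop(sprintf("no matched model for stratum %s", key))
  results <- lapply(scans, function(scan) {
    sm <- .scan_segment_magnitudes(scan, settings)
    if (!isTRUE(all.equal(sm$frequencies, pair$frail_model$frequencies)))
      stop("frequency grid mismatch between spectra and models")
    r <- stats::cor(sm$magnitude, cbind(pair$frail_model$magnitude,
                                        pair$nonfrail_model$magnitude))
    labels <- ifelse(r[, 1] > r[, 2], "frail", "nonfrail")
    fragility_score(split(labels, factor(sm$roi, levels = unique(sm$roi))),
                    correlations = lapply(seq_len(nrow(r)), function(i)
                      c(r_frail = r[i, 1], r_nonfrail = r[i, 2])))
  })
  out <- results[[length(results)]]
  out$fs <- mean(vapply(results, `[[`, numeric(1), "fs"))
  out$stratum <- key
  out
}

#' Build a reference database by streaming simulated reference scans
#'
#' Convenience composition for the synthetic study: for each stratum,
#' simulates `n_per_category` reference subjects (half at f = 1, half at
#' f = 0), runs the FS front-end (envelope, segmentation, ROI, spectra) on
#' each scan, stores the subject's mean segment spectrum, and averages into
#' per-stratum frail/non-frail models. Scans are discarded after use, so
#' memory stays flat.
#'
#' @param strata data.frame with sex, age_bin, bmi_class, site.
#' @param n_per_category Even count per stratum (default 100).
#' @param seed Integer seed.
#' @param templates [spectral_templates()].
#' @param settings [fs_settings()].
#' @param acq Optional acquisition override (default per-site
#'   [acquisition_params()]).
#' @return A `reference_db`.
#' @export
build_reference_database <- function(strata, n_per_category = 100L, seed = 1L,
                                     templates = spectral_templates(),
                                     settings = fs_settings(), acq = NULL) {
  strata <- .as_strata_df(strata)
  if (nrow(strata) == 0) stop("empty strata list")
  if (n_per_category < 2 || n_per_category %% 2 != 0)
    stop("n_per_category must be an even count >= 2")
  strata_out <- list()
  half <- n_per_category / 2L
  for (s in seq_len(nrow(strata))) {
    acq_s <- if (is.null(acq)) acquisition_params(strata$site[s]) else acq
    acc <- list(fractured = NULL, `non-fractured` = NULL)
    grid <- NULL
    for (j in seq_len(n_per_category)) {
      lab <- if (j <= half) "fractured" else "non-fractured"
      f <- if (lab == "fractured") 1 else 0
      sc <- .synthesize_scan(f, acq_s, templates,
                             tissue_seed = derive_seed(seed, (s - 1L) * n_per_category + j))
      sp <- .mean_segment_spectrum(sc, settings)
      if (is.null(grid)) grid <- sp$frequencies
      acc[[lab]] <- if (is.null(acc[[lab]])) sp$magnitude
                    else acc[[lab]] + sp$magnitude
    }
    df <- grid[2] - grid[1]
    norm_model <- function(m) {
      m <- m / half
      structure(list(frequencies = grid, magnitude = m / (sum(m) * df)),
                class = "spectrum_fs")
    }
    strata_out[[.stratum_label(strata[s, ])]] <-
      list(frail_model = norm_model(acc$fractured),
           nonfrail_model = norm_model(acc$`non-fractured`),
           n_frail = half, n_nonfrail = half)
  }
  structure(list(strata = strata_out), class = "reference_db")
}

# Batched front-end: envelope -> trace -> segments -> band-limited unit-area
# periodograms for all segments at once (one FFT batch). Numerically
# identical to compute_spectrum() applied per segment.
.scan_segment_magnitudes <- function(scan, settings = fs_settings()) {
  img <- envelope_image(scan)
  trace <- segment_bone_interface(img, settings$min_depth_margin)
  segs <- select_roi(scan, trace, settings$window_len, settings$offset,
                     settings$min_confidence)
  if (length(segs) == 0) stop("no segments passed the confidence threshold")
  n <- settings$window_len
  X <- vapply(segs, `[[`, numeric(n), "samples") * hann_window(n)
  nfft <- next_pow2(4L * n)
  P <- Mod(stats::mvfft(rbind(X, matrix(0, nfft - n, ncol(X)))))^2
  freqs <- (0:(nfft - 1)) * scan$sampling_rate / nfft
  sel <- which(freqs >= settings$band[1] & freqs <= settings$band[2])
  mag <- P[sel, , drop = FALSE]
  df <- scan$sampling_rate / nfft
  tot <- colSums(mag) * df
  if (any(tot <= 0)) stop("degenerate spectrum")
  list(frequencies = freqs[sel],
       magnitude = sweep(mag, 2, tot, `/`),
       roi = vapply(segs, `[[`, character(1), "roi"))
}

# Mean (renormalised) spectrum over a scan's accepted segments.
.mean_segment_spectrum <- function(scan, settings = fs_settings()) {
  sm <- .scan_segment_magnitudes(scan, settings)
  grid <- sm$frequencies
  m <- rowMeans(sm$magnitude)
  df <- grid[2] - grid[1]
  structure(list(frequencies = grid, magnitude = m / (sum(m) * df)),
            class = "spectrum_fs")
}

#' Score every patient of a cohort through the RF pipeline
#'
#' Simulates one RF scan per patient from their latent fragility and scores
#' it against the reference database, streaming (scans are not retained).
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param db A `reference_db` covering all cohort strata.
#' @param templates,settings,acq Pipeline configuration.
#' @param seed Integer seed for the per-patient scan synthesis.
#' @return The cohort with an added numeric `fs` column.
#' @export
score_cohort <- function(cohort, db, templates = spectral_templates(),
                         settings = fs_settings(), acq = NULL, seed = 1L) {
  site <- cohort$site[1]
  acq_s <- if (is.null(acq)) acquisition_params(site) else acq
  fs <- vapply(seq_len(nrow(cohort)), function(i) {
    p <- cohort[i, ]
    sc <- .synthesize_scan(p$f_latent, acq_s, templates,
                           tissue_seed = derive_seed(seed, i), id = p$id)
    score_patient(sc, p, db, settings)$fs
  }, numeric(1))
  cohort$fs <- fs
  cohort
}

#' Strata present in a cohort
#'
#' @param cohort Cohort data.frame.
#' @return data.frame of the unique (sex, age_bin, bmi_class, site) strata.
#' @export
cohort_strata <- function(cohort) {
  s <- unique(data.frame(sex = cohort$sex,
                         age_bin = age_bin(cohort$age),
                         bmi_class = bmi_class(cohort$bmi),
                         site = cohort$site,
                         stringsAsFactors = FALSE))
  rownames(s) <- NULL
  s
}
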