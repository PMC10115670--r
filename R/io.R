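## Plain-text serialisation: cohort CSV, RF scan collections (JSON manifest
## + TSV matrices), reference database (JSON), diagnostic reports (JSON).

.COHORT_COLUMNS <- c("id", "sex", "age", "height_cm", "weight_kg", "bmi",
                     "site", "f_latent", "dxa_tscore", "rems_tscore",
                     "fractured", "fracture_type", "time_to_event_y")

#' Write / read a cohort table as CSV
#'
#' Numeric columns round-trip losslessly (17 significant digits).
#'
#' @param cohort Cohort data.frame with the full column schema.
#' @param path Output CSV path.
#' @return `write_cohort_csv`: the path, invisibly. `read_cohort_csv`: the
#'   cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  missing_cols <- setdiff(.COHORT_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  data.table::fwrite(cohort, path, dec = ".", sep = ",",
                     dateTimeAs = "ISO", logical01 = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("id", "sex", "site", "fracture_type"))))
  missing_cols <- setdiff(.COHORT_COLUMNS, names(d))
  if (length(missing_cols))
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  d$fractured <- as.logical(d$fractured)
  d
}

#' Write / read an RF scan collection
#'
#' The container is a directory holding `manifest.json` (per-scan metadata:
#' sampling rate, centre frequency, site, ROI partition, ground-truth
#' interface depth, optional label) and one tab-separated matrix file per
#' scan. Arrays round-trip exactly (17 significant digits).
#'
#' @param scans List of `rf_scan` objects.
#' @param path Directory to create/write.
#' @return `write_rf_scans`: the path, invisibly. `read_rf_scans`: list of
#'   `rf_scan` objects.
#' @export
write_rf_scans <- function(scans, path) {
  if (inherits(scans, "rf_scan")) scans <- list(scans)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- lapply(seq_along(scans), function(i) {
    sc <- scans[[i]]
    if (is.null(sc$sampling_rate)) stop("scan lacks sampling_rate attribute")
    fname <- sprintf("scan_%04d.tsv", i)
    # 17 significant digits round-trip doubles exactly
    chr <- formatC(sc$rf, format = "g", digits = 17)
    dim(chr) <- dim(sc$rf)
    data.table::fwrite(as.data.frame(chr), file.path(path, fname),
                       sep = "\t", col.names = FALSE, quote = FALSE)
    m <- sc[setdiff(names(sc), "rf")]
    m$file <- fname
    m
  })
  jsonlite::write_json(meta, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rf_scans
#' @export
read_rf_scans <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  meta <- tryCatch(jsonlite::read_json(mf, simplifyVector = TRUE,
                                       simplifyDataFrame = FALSE),
                   error = function(e) stop("corrupt manifest: ",
                                            conditionMessage(e)))
  lapply(meta, function(m) {
    if (is.null(m$sampling_rate)) stop("scan entry lacks sampling_rate")
    fp <- file.path(path, m$file)
    if (!file.exists(fp)) stop("missing scan data file: ", m$file)
    rf <- as.matrix(data.table::fread(fp, header = FALSE, sep = "\t"))
    dimnames(rf) <- NULL
    sc <- m[setdiff(names(m), "file")]
    sc$rf <- rf
    sc$roi_partition <- unlist(sc$roi_partition)
    if (!is.null(sc$template_choice_truth))
      sc$template_choice_truth <- unlist(sc$template_choice_truth)
    class(sc) <- "rf_scan"
    sc
  })
}

#' Write / read a reference database as JSON
#'
#' Stores, per stratum, the frequency grid, both model magnitudes and the
#' member counts.
#'
#' @param db A `reference_db`.
#' @param path Output JSON path.
#' @return `write_reference_db`: the path, invisibly. `read_reference_db`:
#'   the `reference_db`.
#' @export
write_reference_db <- function(db, path) {
  out <- lapply(db$strata, function(p) list(
    frequencies = p$frail_model$frequencies,
    frail = p$frail_model$magnitude,
    nonfrail = p$nonfrail_model$magnitude,
    n_frail = p$n_frail, n_nonfrail = p$n_nonfrail))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  strata <- lapply(raw, function(p) {
    grid <- unlist(p$frequencies)
    list(frail_model = structure(list(frequencies = grid,
                                      magnitude = unlist(p$frail)),
                                 class = "spectrum_fs"),
         nonfrail_model = structure(list(frequencies = grid,
                                         magnitude = unlist(p$nonfrail)),
                                    class = "spectrum_fs"),
         n_frail = p$n_frail, n_nonfrail = p$n_nonfrail)
  })
  structure(list(strata = strata), class = "reference_db")
}

#' Write a diagnostic report (or any result list) as JSON
#'
#' Embeds the seed and a digest of the settings so re-runs are verifiable.
#'
#' @param report A `diagnostic_report` or plain list.
#' @param path Output JSON path.
#' @param seed Optional seed to embed.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path, seed = NULL) {
  rep <- unclass(report)
  rep$roc <- NULL  # curves are written separately as CSV when needed
  if (!is.null(seed)) rep$seed <- seed
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Write ROC curve points as CSV
#'
#' @param r A `roc_result`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_roc_csv <- function(r, path) {
  data.table::fwrite(data.frame(threshold = r$thresholds,
                                fpr = r$fpr, tpr = r$tpr), path)
  invisible(path)
}
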