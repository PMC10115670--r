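## Cohort-level diagnostic accuracy statistics: group comparison, ROC/AUC
## with DeLong placement components, Youden cut-off, confusion-table
## metrics, odds ratios, covariate-adjusted ROC.

#' Construct a marker series
#'
#' A per-patient diagnostic marker with its orientation. FS is
#' higher-is-positive; T-scores are lower-is-positive (more negative =
#' higher risk).
#'
#' @param values Numeric scores.
#' @param labels Logical (or 0/1) incident-fracture indicators.
#' @param direction `"higher_is_positive"` or `"lower_is_positive"`.
#' @return A `marker_series`.
#' @export
marker_series <- function(values, labels,
                          direction = c("higher_is_positive",
                                        "lower_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), all(is.finite(values)),
            !anyNA(labels))
  structure(list(values = values, labels = labels, direction = direction),
            class = "marker_series")
}

# Scores oriented so that larger = more indicative of disease.
.oriented <- function(m) {
  if (m$direction == "lower_is_positive") -m$values else m$values
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation (type-7), the convention used for
#' cohort descriptive tables.
#'
#' @param x Non-empty numeric vector.
#' @return List with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(x) {
  if (length(x) == 0) stop("empty input")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Mann-Whitney U test
#'
#' U is computed with midranks under ties. For small samples (both groups
#' <= 8) the two-sided p-value is obtained by exact enumeration over all
#' assignments of the pooled observations to groups; otherwise by the
#' normal approximation with tie correction (via [stats::wilcox.test()]).
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `U` (for the first sample) and `p_two_sided`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= 8 && ny <= 8) {
    # exact: U for every choice of nx pooled ranks
    combs <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    # two-sided via distance of U from its null mean
    mu <- nx * ny / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  }
  list(U = U, p_two_sided = min(1, p))
}

#' ROC curve with DeLong placement components
#'
#' Scores are oriented so that larger means more positive; thresholds are
#' the unique oriented score values (call rule: positive iff score >=
#' threshold), plus a sentinel above the maximum. AUC is the trapezoidal
#' area, which equals the Mann-Whitney concordance probability with ties
#' counted one half. Per-subject placement values (the structural
#' components of the DeLong variance estimator) are stored.
#'
#' @param m A `marker_series` with both classes present.
#' @return A `roc_result`: `thresholds`, `fpr`, `tpr`, `auc`, and placement
#'   values `v_pos` (one per diseased) and `v_neg` (one per non-diseased).
#' @export
roc_curve <- function(m) {
  s <- .oriented(m)
  pos <- s[m$labels]; neg <- s[!m$labels]
  if (length(pos) == 0 || length(neg) == 0) stop("single-class input")
  ord <- order(s, decreasing = TRUE)
  ss <- s[ord]; ll <- m$labels[ord]
  grp_end <- cumsum(rle(ss)$lengths)    # last index of each tie group
  thr <- c(Inf, ss[grp_end])
  tpr <- c(0, cumsum(ll)[grp_end] / length(pos))
  fpr <- c(0, cumsum(!ll)[grp_end] / length(neg))
  # placement values: for diseased i, fraction of non-diseased scored below
  # (ties one half); symmetric for non-diseased
  rk <- rank(c(pos, neg), ties.method = "average")
  np <- length(pos); nn <- length(neg)
  v_pos <- (rk[seq_len(np)] - rank(pos, ties.method = "average")) / nn
  v_neg <- 1 - (rk[np + seq_len(nn)] - rank(neg, ties.method = "average")) / np
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 v_pos = v_pos, v_neg = v_neg,
                 n_pos = np, n_neg = nn, direction = m$direction),
            class = "roc_result")
}

# DeLong variance of a single AUC from placement components.
.auc_variance <- function(r) {
  stats::var(r$v_pos) / r$n_pos + stats::var(r$v_neg) / r$n_neg
}

#' DeLong test for two paired AUCs
#'
#' Both markers must score the same subjects with identical labels. The
#' variance of the AUC difference is estimated from the per-subject
#' placement values (structural components), honouring their correlation;
#' the p-value is two-sided normal.
#'
#' @param a,b `marker_series` objects on the same subjects.
#' @return List: `auc_a`, `auc_b`, `diff`, `se_diff`, `z`, `p`.
#' @export
delong_compare <- function(a, b) {
  if (length(a$values) != length(b$values) || !identical(a$labels, b$labels))
    stop("unpaired inputs: markers must share subjects and labels")
  ra <- roc_curve(a); rb <- roc_curve(b)
  d_pos <- ra$v_pos - rb$v_pos
  d_neg <- ra$v_neg - rb$v_neg
  se <- sqrt(stats::var(d_pos) / ra$n_pos + stats::var(d_neg) / ra$n_neg)
  diff <- ra$auc - rb$auc
  if (se == 0) {
    z <- 0; p <- 1
  } else {
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ra$auc, auc_b = rb$auc, diff = diff, se_diff = se, z = z, p = p)
}

#' Youden-optimal cut-off
#'
#' The threshold (on the oriented scale, call rule >=) maximising Youden's
#' J = sensitivity + specificity - 1, the standard reading of "best
#' trade-off between sensitivity and specificity". Ties are broken towards
#' the smallest oriented threshold.
#'
#' @param r A `roc_result`.
#' @return The optimal threshold (finite, attained in the data).
#' @export
optimal_cutoff <- function(r) {
  finite <- is.finite(r$thresholds)
  if (sum(finite) < 2) stop("degenerate ROC: all scores equal")
  j <- r$tpr - r$fpr
  j <- j[finite]; thr <- r$thresholds[finite]
  best <- max(j)
  min(thr[j >= best - 1e-12])
}

#' Confusion table at a cut-off
#'
#' A subject is called positive iff their oriented score is >= the
#' threshold.
#'
#' @param m A `marker_series`.
#' @param threshold Cut-off on the oriented scale.
#' @return A `confusion_table`: list with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_at_cutoff <- function(m, threshold) {
  s <- .oriented(m)
  call_pos <- s >= threshold
  structure(list(tp = sum(call_pos & m$labels),
                 fn = sum(!call_pos & m$labels),
                 fp = sum(call_pos & !m$labels),
                 tn = sum(!call_pos & !m$labels)),
            class = "confusion_table")
}

#' Reconstruct a confusion table from printed rates and group sizes
#'
#' Given a published sensitivity and specificity (percent) and the diseased
#' and non-diseased group sizes, recovers the integer 2x2 table by
#' nearest-integer rounding (half away from zero). Published predictive
#' values and odds ratios follow arithmetically from the result.
#'
#' @param sens,spec Percentages in \[0, 100].
#' @param n_pos,n_neg Positive group sizes.
#' @return A `confusion_table`.
#' @export
confusion_from_rates <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 100, spec >= 0, spec <= 100,
            n_pos > 0, n_neg > 0)
  tp <- round_half_away(sens / 100 * n_pos)
  tn <- round_half_away(spec / 100 * n_neg)
  t <- list(tp = tp, fn = n_pos - tp, fp = n_neg - tn, tn = tn)
  if (any(unlist(t) < 0)) stop("rounding yields a negative cell")
  structure(t, class = "confusion_table")
}

#' Sensitivity, specificity, PPV and NPV of a confusion table
#'
#' Percentages with full precision; rounding belongs to presentation only.
#' A metric with a zero denominator is returned as `NA` with a warning,
#' never silently as zero.
#'
#' @param t A `confusion_table`.
#' @return List of percents: `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
diagnostic_metrics <- function(t) {
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NA_real_)
    }
    100 * num / den
  }
  list(sensitivity = safe(t$tp, t$tp + t$fn, "sensitivity"),
       specificity = safe(t$tn, t$tn + t$fp, "specificity"),
       ppv = safe(t$tp, t$tp + t$fp, "PPV"),
       npv = safe(t$tn, t$tn + t$fn, "NPV"))
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = (tp tn)/(fn fp); the confidence interval is the log-scale Wald
#' (Woolf) interval and the p-value the corresponding two-sided z test. A
#' single zero cell triggers the Haldane-Anscombe 0.5 correction on all
#' cells (flagged in the result); two zero cells in the same margin make
#' the table degenerate.
#'
#' @param t A `confusion_table`.
#' @param alpha Significance level (default 0.05 for a 95% CI).
#' @return List: `or`, `ci_low`, `ci_high`, `p`, `haldane`.
#' @export
odds_ratio <- function(t, alpha = 0.05) {
  cells <- c(t$tp, t$fn, t$fp, t$tn)
  stopifnot(all(cells >= 0))
  zero <- cells == 0
  if ((zero[1] && zero[2]) || (zero[3] && zero[4]) ||
      (zero[1] && zero[3]) || (zero[2] && zero[4]))
    stop("degenerate table")
  haldane <- any(zero)
  if (haldane) cells <- cells + 0.5
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       p = 2 * stats::pnorm(-abs(log(or)) / se),
       haldane = haldane)
}

#' Covariate adjustment of a marker by residual linear fitting
#'
#' Ordinary least squares of the score on the covariates (with intercept),
#' fitted on the non-diseased subjects only; the adjusted score of every
#' subject is their residual from that fit. This is the residual approach
#' to covariate-adjusted ROC analysis: the adjusted marker measures what
#' the score adds beyond the covariates' normal-population trend.
#'
#' @param m A `marker_series`.
#' @param covariates data.frame (or matrix) of per-patient covariates.
#' @return A `marker_series` of residuals, direction preserved.
#' @export
covariate_adjust <- function(m, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(m$values), !anyNA(covariates))
  if (length(m$values) < ncol(covariates) + 2)
    stop("need at least two more subjects than covariates")
  dat <- cbind(score = m$values, covariates)
  fit <- stats::lm(score ~ ., data = dat[!m$labels, , drop = FALSE])
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  adj <- m$values - stats::predict(fit, newdata = dat)
  marker_series(unname(adj), m$labels, m$direction)
}

#' Full diagnostic evaluation of one marker
#'
#' Optionally adjusts for covariates, then computes the ROC curve and AUC
#' (with a DeLong-variance p-value against AUC = 0.5), the Youden cut-off,
#' the confusion table and its metrics at that cut-off, and the odds ratio.
#' For T-score markers the conventional osteoporosis threshold (T-score
#' <= -2.5) can be evaluated in addition via `fixed_cutoff`.
#'
#' @param cohort Cohort data.frame.
#' @param marker Column name of the marker.
#' @param label_col Column with the fracture indicator (default
#'   "fractured").
#' @param direction Marker orientation.
#' @param covariates Character vector of covariate column names, or NULL.
#' @param fixed_cutoff Optional cut-off on the marker's natural scale
#'   (e.g. -2.5 for T-scores, rule <= for lower-is-positive markers).
#' @return A `diagnostic_report` list.
#' @export
evaluate_marker <- function(cohort, marker, label_col = "fractured",
                            direction = c("higher_is_positive",
                                          "lower_is_positive"),
                            covariates = NULL, fixed_cutoff = NULL) {
  direction <- match.arg(direction)
  m <- marker_series(cohort[[marker]], cohort[[label_col]], direction)
  if (!is.null(covariates))
    m <- covariate_adjust(m, cohort[, covariates, drop = FALSE])
  r <- roc_curve(m)
  se_auc <- sqrt(.auc_variance(r))
  auc_p <- if (se_auc == 0) NA_real_ else 2 * stats::pnorm(-abs(r$auc - 0.5) / se_auc)
  cut <- optimal_cutoff(r)
  tab <- confusion_at_cutoff(m, cut)
  met <- diagnostic_metrics(tab)
  or <- odds_ratio(tab)
  # report the cut-off on the marker's natural scale
  cut_natural <- if (direction == "lower_is_positive") -cut else cut
  rep <- list(marker = marker, adjusted_for = covariates,
              auc = r$auc, auc_p = auc_p,
              cutoff = cut_natural,
              cutoff_rule = if (direction == "lower_is_positive") "<=" else ">=",
              sensitivity = met$sensitivity, specificity = met$specificity,
              ppv = met$ppv, npv = met$npv,
              or = or$or, or_ci_low = or$ci_low, or_ci_high = or$ci_high,
              or_p = or$p,
              n_pos = r$n_pos, n_neg = r$n_neg,
              roc = r)
  if (!is.null(fixed_cutoff)) {
    cut_o <- if (direction == "lower_is_positive") -fixed_cutoff else fixed_cutoff
    tab_f <- confusion_at_cutoff(m, cut_o)
    rep$fixed <- c(list(cutoff = fixed_cutoff),
                   diagnostic_metrics(tab_f), odds_ratio(tab_f))
  }
  structure(rep, class = "diagnostic_report")
}
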