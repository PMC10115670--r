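test_that("median and IQR use type-7 quantiles", {
  m <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(m$median, 3); expect_equal(m$q1, 2); expect_equal(m$q3, 4)
  m2 <- median_iqr(rep(7, 10))
  expect_equal(m2$q1, m2$median); expect_equal(m2$median, m2$q3)
  expect_error(median_iqr(numeric(0)), "empty")

  # sorted-array interpolation oracle
  set.seed(3)
  x <- rnorm(101)
  s <- sort(x)
  h <- function(p) { k <- (length(x) - 1) * p
    s[floor(k) + 1] + (k - floor(k)) * (s[floor(k) + 2 - (k == floor(k))] -
                                          s[floor(k) + 1]) }
  m3 <- median_iqr(x)
  expect_equal(m3$q1, h(0.25)); expect_equal(m3$median, h(0.5))
  expect_equal(m3$q3, h(0.75))
})

test_that("Mann-Whitney U handles extreme orderings and identical groups", {
  r <- mann_whitney_u(1:4, 5:8)
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 2 / choose(8, 4))
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_two_sided, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty group")
})

test_that("small-sample Mann-Whitney matches exhaustive enumeration", {
  # independent oracle: enumerate all 70 assignments, U by pair counting
  u_pairs <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  set.seed(11)
  for (rep in 1:5) {
    pooled <- round(rnorm(8), 2)
    x <- pooled[1:4]; y <- pooled[5:8]
    obs <- u_pairs(x, y)
    combs <- combn(8, 4)
    u_all <- apply(combs, 2, function(ix) u_pairs(pooled[ix], pooled[-ix]))
    p_oracle <- mean(abs(u_all - 8) >= abs(obs - 8) - 1e-9)
    r <- mann_whitney_u(x, y)
    expect_equal(r$U, obs)
    expect_equal(r$p_two_sided, p_oracle)
  }
})

test_that("large-sample Mann-Whitney agrees with the normal approximation", {
  set.seed(4)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  expect_equal(mann_whitney_u(x, y)$p_two_sided,
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
})

test_that("ROC: separation, orientation, curve validity", {
  m <- marker_series(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  r <- roc_curve(m)
  expect_equal(r$auc, 1)
  expect_true(all(diff(r$fpr) >= 0), all(diff(r$tpr) >= 0))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))

  # lower_is_positive orientation: negated scores give the same curve
  mt <- marker_series(-c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE),
                      "lower_is_positive")
  expect_equal(roc_curve(mt)$auc, 1)
  expect_error(roc_curve(marker_series(1:4, rep(TRUE, 4))), "single-class")
})

test_that("AUC equals the pair-counting concordance on random instances", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    scores <- sample(round(rnorm(n), 1))   # coarse values force ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    r <- roc_curve(marker_series(scores, labels))
    expect_equal(r$auc, auc_pair_counting(scores, labels), tolerance = 1e-12)
    # placement means reproduce the AUC
    expect_equal(mean(r$v_pos), r$auc, tolerance = 1e-12)
    expect_equal(mean(r$v_neg), r$auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(23)
  scores <- rnorm(60); labels <- rep(c(TRUE, FALSE), 30)
  a <- roc_curve(marker_series(scores, labels))$auc
  b <- roc_curve(marker_series(exp(2 * scores) + 5, labels))$auc
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("null-model AUC concentrates at one half", {
  set.seed(29)
  aucs <- replicate(200, {
    roc_curve(marker_series(rnorm(2000),
                            sample(c(TRUE, FALSE), 2000, replace = TRUE)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("DeLong: self-comparison, rank invariance, pROC agreement", {
  set.seed(37)
  labels <- rep(c(TRUE, FALSE), c(25, 35))
  a <- marker_series(rnorm(60) + labels, labels)
  self <- delong_compare(a, a)
  expect_equal(self$diff, 0); expect_equal(self$p, 1)

  b <- marker_series(qlogis(plogis(a$values))^1 * 3 + 2, labels)  # monotone
  expect_equal(delong_compare(a, b)$diff, 0, tolerance = 1e-12)

  c_ <- marker_series(rnorm(60) + 0.5 * labels, labels)
  res <- delong_compare(a, c_)
  expect_gte(res$se_diff, 0)
  pr <- pROC::roc.test(pROC::roc(labels, a$values, quiet = TRUE,
                                 direction = "<"),
                       pROC::roc(labels, c_$values, quiet = TRUE,
                                 direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(res$p, pr$p.value, tolerance = 1e-9)
  expect_error(delong_compare(a, marker_series(rnorm(10), rep(c(TRUE, FALSE), 5))),
               "unpaired")
})

test_that("Youden cut-off maximises J with smallest-threshold tie-break", {
  m <- marker_series(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(optimal_cutoff(roc_curve(m)), 3)

  # exhaustive oracle on a 20-point instance
  set.seed(41)
  scores <- round(rnorm(20), 1)
  labels <- rep(c(TRUE, FALSE), 10)
  r <- roc_curve(marker_series(scores, labels))
  js <- vapply(unique(scores), function(t) {
    sens <- mean(scores[labels] >= t); spec <- mean(scores[!labels] < t)
    sens + spec - 1 }, numeric(1))
  expect_equal(optimal_cutoff(r),
               min(unique(scores)[js >= max(js) - 1e-12]))

  expect_error(optimal_cutoff(roc_curve(marker_series(rep(1, 6),
                                                      rep(c(TRUE, FALSE), 3)))),
               "degenerate ROC")
})

test_that("symmetric overlapping classes put the cut-off near the midpoint", {
  set.seed(43)
  n <- 20000
  scores <- c(rnorm(n, 0), rnorm(n, 1))
  labels <- rep(c(FALSE, TRUE), each = n)
  cut <- optimal_cutoff(roc_curve(marker_series(scores, labels)))
  expect_lt(abs(cut - 0.5), 0.1)
})

test_that("confusion tables at cut-offs match hand counts", {
  m <- marker_series(c(5, 3, 8, 1, 9, 2, 7, 4, 6, 0),
                     c(TRUE, FALSE, TRUE, FALSE, TRUE,
                       FALSE, FALSE, TRUE, FALSE, FALSE))
  lo <- confusion_at_cutoff(m, -1)
  expect_equal(c(lo$fn, lo$tn), c(0, 0))
  hi <- confusion_at_cutoff(m, 100)
  expect_equal(c(hi$tp, hi$fp), c(0, 0))
  t6 <- confusion_at_cutoff(m, 6)   # scores >= 6: {8, 9, 7, 6}
  expect_equal(unlist(t6[c("tp", "fn", "fp", "tn")]), c(tp = 2, fn = 2,
                                                        fp = 2, tn = 4))
})

test_that("confusion reconstruction from printed rates", {
  t <- confusion_from_rates(72.4, 77.9, 181, 1108)
  expect_equal(unlist(t[c("tp", "fn", "fp", "tn")]),
               c(tp = 131, fn = 50, fp = 245, tn = 863))
  t2 <- confusion_from_rates(100, 100, 10, 20)
  expect_equal(unlist(t2[c("tp", "fn", "fp", "tn")]),
               c(tp = 10, fn = 0, fp = 0, tn = 20))
  t3 <- confusion_from_rates(50, 50, 4, 4)
  expect_equal(unlist(t3[c("tp", "fn", "fp", "tn")]),
               c(tp = 2, fn = 2, fp = 2, tn = 2))
})

test_that("diagnostic metrics reproduce published predictive values", {
  m1 <- diagnostic_metrics(structure(list(tp = 131, fn = 50, fp = 245,
                                          tn = 863), class = "confusion_table"))
  expect_equal(round(m1$ppv, 1), 34.8)
  expect_equal(round(m1$npv, 1), 94.5)
  m2 <- diagnostic_metrics(structure(list(tp = 13, fn = 5, fp = 109,
                                          tn = 347), class = "confusion_table"))
  expect_equal(round(m2$ppv, 1), 10.7)
  expect_equal(round(m2$npv, 1), 98.6)
  perfect <- diagnostic_metrics(structure(list(tp = 10, fn = 0, fp = 0,
                                               tn = 20), class = "confusion_table"))
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  ppv = 100, npv = 100))
  expect_warning(
    res <- diagnostic_metrics(structure(list(tp = 0, fn = 0, fp = 3, tn = 7),
                                        class = "confusion_table")),
    "undefined")
  expect_true(is.na(res$sensitivity))
})

test_that("odds ratios with Woolf intervals match published values", {
  o1 <- odds_ratio(structure(list(tp = 131, fn = 50, fp = 245, tn = 863),
                             class = "confusion_table"))
  expect_equal(round(o1$or, 2), 9.23)
  expect_equal(round(o1$ci_low, 2), 6.47)
  expect_equal(round(o1$ci_high, 2), 13.17)
  expect_lt(o1$p, 0.0001)

  o2 <- odds_ratio(structure(list(tp = 21, fn = 9, fp = 315, tn = 860),
                             class = "confusion_table"))
  expect_equal(round(o2$or, 2), 6.37)

  o3 <- odds_ratio(structure(list(tp = 2, fn = 2, fp = 2, tn = 2),
                             class = "confusion_table"))
  expect_equal(o3$or, 1)
  expect_equal(log(o3$ci_low), -log(o3$ci_high), tolerance = 1e-12)

  # transposing the labels inverts the OR
  o4 <- odds_ratio(structure(list(tp = 50, fn = 131, fp = 863, tn = 245),
                             class = "confusion_table"))
  expect_equal(o4$or, 1 / o1$or, tolerance = 1e-12)

  oz <- odds_ratio(structure(list(tp = 0, fn = 4, fp = 3, tn = 7),
                             class = "confusion_table"))
  expect_true(oz$haldane)
  expect_error(odds_ratio(structure(list(tp = 0, fn = 0, fp = 3, tn = 7),
                                    class = "confusion_table")), "degenerate")
})

test_that("covariate adjustment by residual linear fitting", {
  set.seed(47)
  age <- runif(200, 40, 80)
  labels <- rep(c(TRUE, FALSE), 100)
  m_exact <- marker_series(2 + 3 * age, labels)
  adj <- covariate_adjust(m_exact, data.frame(age = age))
  expect_true(all(abs(adj$values) < 1e-9))

  m <- marker_series(rnorm(200) + labels, labels)
  adj1 <- covariate_adjust(m, data.frame(age = age))
  m_shift <- marker_series(m$values + 42, labels)
  adj2 <- covariate_adjust(m_shift, data.frame(age = age))
  expect_equal(adj1$values, adj2$values, tolerance = 1e-9)

  expect_error(covariate_adjust(m, data.frame(a = age, b = 2 * age)),
               "rank-deficient")
})

test_that("adjusting for an independent covariate leaves the AUC alone", {
  set.seed(53)
  n <- 2000
  labels <- rep(c(TRUE, FALSE), n / 2)
  scores <- rnorm(n) + labels
  cov_ind <- rnorm(n)
  m <- marker_series(scores, labels)
  auc0 <- roc_curve(m)$auc
  auc1 <- roc_curve(covariate_adjust(m, data.frame(x = cov_ind)))$auc
  expect_lt(abs(auc1 - auc0), 0.02)
})

test_that("evaluate_marker composes the full report", {
  co <- generate_cohort(600, seed = 61)
  co$fs <- 100 * co$f_latent
  rep <- evaluate_marker(co, "fs")
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true(rep$cutoff %in% co$fs)
  expect_true(all(c("sensitivity", "specificity", "ppv", "npv", "or") %in%
                    names(rep)))

  co$perfect <- 100 * co$fractured
  rp <- evaluate_marker(co, "perfect")
  expect_equal(rp$auc, 1)
  expect_equal(rp$sensitivity, 100)
  expect_equal(rp$specificity, 100)

  # T-score marker with the conventional fixed cut-off
  rt <- evaluate_marker(co, "rems_tscore", direction = "lower_is_positive",
                        fixed_cutoff = -2.5)
  expect_equal(rt$fixed$cutoff, -2.5)
  manual <- confusion_at_cutoff(
    marker_series(co$rems_tscore, co$fractured, "lower_is_positive"), 2.5)
  expect_equal(rt$fixed$sensitivity,
               100 * manual$tp / (manual$tp + manual$fn))
})

test_that("rate reconstruction round-trips within the rounding bound", {
  cases <- list(c(72.4, 77.9, 181, 1108), c(70.0, 73.2, 30, 1175),
                c(71.6, 79.0, 67, 448), c(72.2, 76.1, 18, 456))
  for (cs in cases) {
    t <- confusion_from_rates(cs[1], cs[2], cs[3], cs[4])
    met <- diagnostic_metrics(t)
    expect_lte(abs(met$sensitivity - cs[1]), 100 * 0.5 / cs[3])
    expect_lte(abs(met$specificity - cs[2]), 100 * 0.5 / cs[4])
  }
})
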