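#!/usr/bin/env Rscript
# Stage 4 — diagnostic-accuracy evaluation.
#
# Per sex and site: ROC/AUC of FS and of both T-scores, Youden cut-off with
# sensitivity / specificity / PPV / NPV / OR, paired DeLong comparisons of
# FS against each T-score, and age- and BMI-adjusted AUCs (residual linear
# fitting on the non-fractured group). Also reconstructs the published
# 2x2 tables from printed rates and group counts as an arithmetic check.
# Requires stage 3 outputs.

suppressPackageStartupMessages(library(remsfs))

fmt_rep <- function(r)
  sprintf("AUC %.3f (p %.2g)  cutoff %.4g  sens %.1f%%  spec %.1f%%  PPV %.1f%%  NPV %.1f%%  OR %.2f (%.2f-%.2f)",
          r$auc, r$auc_p, r$cutoff, r$sensitivity, r$specificity,
          r$ppv, r$npv, r$or, r$or_ci_low, r$or_ci_high)

rows <- list()
for (site in c("lumbar", "femur")) {
  co <- as.data.frame(data.table::fread(
    sprintf("results/cohort_%s_scored.csv", site)))
  co$fractured <- as.logical(co$fractured)
  for (sx in c("F", "M")) {
    sub <- co[co$sex == sx, ]
    cat(sprintf("\n== %s / %s (n = %d, %d fractures) ==\n",
                sx, site, nrow(sub), sum(sub$fractured)))
    fs_rep <- evaluate_marker(sub, "fs")
    rem_rep <- evaluate_marker(sub, "rems_tscore",
                               direction = "lower_is_positive",
                               fixed_cutoff = -2.5)
    dxa_rep <- evaluate_marker(sub, "dxa_tscore",
                               direction = "lower_is_positive",
                               fixed_cutoff = -2.5)
    cat(" FS      :", fmt_rep(fs_rep), "\n")
    cat(" REMS T  :", fmt_rep(rem_rep), "\n")
    cat(" DXA T   :", fmt_rep(dxa_rep), "\n")
    cat(sprintf(" REMS T at T<=-2.5: OR %.2f (%.2f-%.2f)\n",
                rem_rep$fixed$or, rem_rep$fixed$ci_low, rem_rep$fixed$ci_high))

    mk <- function(cl, d) marker_series(sub[[cl]], sub$fractured, d)
    dl_r <- delong_compare(mk("fs", "higher_is_positive"),
                           mk("rems_tscore", "lower_is_positive"))
    dl_d <- delong_compare(mk("fs", "higher_is_positive"),
                           mk("dxa_tscore", "lower_is_positive"))
    cat(sprintf(" DeLong FS vs REMS T: diff %.3f, p %.2g; FS vs DXA T: diff %.3f, p %.2g\n",
                dl_r$diff, dl_r$p, dl_d$diff, dl_d$p))

    fs_adj <- evaluate_marker(sub, "fs", covariates = c("age", "bmi"))
    rem_adj <- evaluate_marker(sub, "rems_tscore",
                               direction = "lower_is_positive",
                               covariates = c("age", "bmi"))
    dxa_adj <- evaluate_marker(sub, "dxa_tscore",
                               direction = "lower_is_positive",
                               covariates = c("age", "bmi"))
    cat(sprintf(" age+BMI-adjusted AUC: FS %.3f, REMS T %.3f, DXA T %.3f\n",
                fs_adj$auc, rem_adj$auc, dxa_adj$auc))

    write_report_json(fs_rep, sprintf("results/report_fs_%s_%s.json", site, sx))
    write_roc_csv(fs_rep$roc, sprintf("results/roc_fs_%s_%s.csv", site, sx))
    rows[[paste(site, sx)]] <- data.frame(
      site = site, sex = sx, n = nrow(sub),
      fs_auc = fs_rep$auc, rems_auc = rem_rep$auc, dxa_auc = dxa_rep$auc,
      fs_auc_adj = fs_adj$auc, rems_auc_adj = rem_adj$auc,
      dxa_auc_adj = dxa_adj$auc,
      fs_cutoff = fs_rep$cutoff, delong_p_rems = dl_r$p,
      delong_p_dxa = dl_d$p)
  }
}
write.csv(do.call(rbind, rows), "results/marker_summary.csv",
          row.names = FALSE)

cat("\n== reconstruction of the published 2x2 tables ==\n")
recon <- list(women_lumbar = c(72.4, 77.9, 181, 1108),
              women_femur = c(70.0, 73.2, 30, 1175),
              men_lumbar = c(71.6, 79.0, 67, 448),
              men_femur = c(72.2, 76.1, 18, 456))
for (nm in names(recon)) {
  cs <- recon[[nm]]
  tab <- confusion_from_rates(cs[1], cs[2], cs[3], cs[4])
  o <- odds_ratio(tab); met <- diagnostic_metrics(tab)
  cat(sprintf(" %-13s tp=%3d fn=%2d fp=%3d tn=%3d  OR %.2f (%.2f-%.2f)  PPV %.1f%%  NPV %.1f%%\n",
              nm, tab$tp, tab$fn, tab$fp, tab$tn, o$or, o$ci_low, o$ci_high,
              round_half_away(met$ppv, 1), round_half_away(met$npv, 1)))
}
cat("\nsummary written to results/marker_summary.csv\n")
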