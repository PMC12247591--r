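#!/usr/bin/env Rscript
# ROC discrimination: how well wCPL and cortical complexity identify PTSD
# (any PTSD, and PTSD without MDD), alone and combined with demographics by
# in-sample logistic scoring. DeLong 95% confidence intervals throughout.

library(connectopath)

dat <- read_results("results/metrics.csv")

fc <- feature_correlation(dat$wcpl, dat$cortical_complexity,
                          contrast = "wcpl_vs_cortical_complexity")
cat(sprintf("wCPL vs cortical complexity: rho = %.2f, p = %.3f\n",
            fc$estimate, fc$p))

rows <- list()
specs <- list(any_ptsd = rep(TRUE, nrow(dat)),
              ptsd_no_mdd = !(dat$group == "ptsd" & dat$mdd))
for (nm in names(specs)) {
  sel <- specs[[nm]]
  y <- dat$group[sel] == "ptsd"
  for (feat in c("wcpl", "cortical_complexity")) {
    r <- roc_auc(dat[[feat]][sel], y)
    rows[[paste(nm, feat)]] <- data.frame(
      label = nm, feature = feat, auc = r$auc, ci_low = r$ci_low,
      ci_high = r$ci_high, n_pos = r$n_pos, n_neg = r$n_neg)
    cat(sprintf("%s / %-20s AUC = %.2f [%.2f-%.2f]\n", nm, feat, r$auc,
                r$ci_low, r$ci_high))
  }
  cs <- combined_score(dat[sel, c("wcpl", "cortical_complexity")], y,
                       dat[sel, c("age", "education", "body_mass")])
  r <- cs$roc
  rows[[paste(nm, "combined")]] <- data.frame(
    label = nm, feature = "combined", auc = r$auc, ci_low = r$ci_low,
    ci_high = r$ci_high, n_pos = r$n_pos, n_neg = r$n_neg)
  cat(sprintf("%s / %-20s AUC = %.2f [%.2f-%.2f] (%s)\n", nm, "combined",
              r$auc, r$ci_low, r$ci_high, cs$note))
}
write.table(do.call(rbind, rows), "results/roc.csv", sep = ",",
            row.names = FALSE, quote = FALSE)
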