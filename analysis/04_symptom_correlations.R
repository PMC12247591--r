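#!/usr/bin/env Rscript
# Multivariable-adjusted Spearman correlations between wCPL and PTSD symptom
# domains, in the overlapping clinical subgroups (participants without MDD,
# with PTSD, with PTSD and MDD), with BH-FDR control per subgroup.

library(connectopath)

dat <- read_results("results/metrics.csv")
covars <- dat[, c("age", "sex", "education", "body_mass")]
domains <- c("re_experiencing", "avoidance", "hyperarousal",
             "negative_affect", "overall")
subgroups <- list(no_mdd = !dat$mdd,
                  ptsd = dat$group == "ptsd",
                  ptsd_mdd = dat$group == "ptsd" & dat$mdd)

out <- list()
for (sg in names(subgroups)) {
  sel <- subgroups[[sg]]
  rows <- lapply(domains, function(dom) {
    adjusted_spearman(dat$wcpl[sel], dat[[dom]][sel], covars[sel, ],
                      contrast = paste0(sg, ":", dom))
  })
  tab <- bind_results(rows)
  fdr <- bh_fdr(tab$p, alpha = 0.05)
  tab$p_adjusted <- fdr$p_adjusted
  tab$fdr_pass <- fdr$rejected
  out[[sg]] <- tab
  cat(sprintf("%s (n = %d):\n", sg, sum(sel)))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-16s rho = %+.2f, p = %.3f%s\n", domains[i],
                tab$estimate[i], tab$p[i],
                if (tab$fdr_pass[i]) "  [passes FDR]" else ""))
  }
}
write_results(do.call(rbind, out), "results/correlations.csv")
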