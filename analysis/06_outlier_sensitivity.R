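#!/usr/bin/env Rscript
# Post-hoc sensitivity: repeat the main wCPL contrasts after removing the 3
# highest-wCPL subjects within the PTSD group, and report how many subjects
# exceed the wCPL reporting threshold (80) and how many of those are PTSD+.

library(connectopath)

dat <- read_results("results/metrics.csv")
dat$group <- factor(dat$group, levels = group_levels(), ordered = TRUE)

analysis <- function(d) {
  bind_results(list(
    welch_t(d$wcpl[d$group == "ptsd"], d$wcpl[d$group == "exposed_noptsd"],
            contrast = "ptsd_vs_exposed_noptsd"),
    welch_t(d$wcpl[d$group == "ptsd"], d$wcpl[d$group != "ptsd"],
            contrast = "ptsd_vs_all_nonptsd")))
}
sens <- outlier_sensitivity(dat, group = "ptsd", k = 3, analysis = analysis,
                            threshold = 80)
full <- sens$full; full$sample <- "full"
trimmed <- sens$trimmed; trimmed$sample <- "trimmed"
write_results(rbind(full, trimmed), "results/sensitivity.csv")

cat("Removed (top-3 wCPL in PTSD group):",
    paste(sens$removed_ids, collapse = ", "), "\n")
for (i in seq_len(nrow(full))) {
  cat(sprintf("%-26s full: d = %.2f, p = %.4f | trimmed: d = %.2f, p = %.4f\n",
              full$contrast[i], full$effect_size[i], full$p[i],
              trimmed$effect_size[i], trimmed$p[i]))
}
cat(sprintf("Subjects with wCPL > 80: %d (%d in the PTSD group)\n",
            sens$n_above_threshold, sens$n_above_threshold_in_group))
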