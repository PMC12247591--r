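# End-to-end orchestration: simulate (or load) -> per-subject metrics ->
# contrasts / correlations / ROC / sensitivity -> manifest + report.

symptom_domains <- function() {
  c("re_experiencing", "avoidance", "hyperarousal", "negative_affect",
    "overall")
}

# Table-2-style overlapping subgroups
analysis_subgroups <- function(records) {
  list(no_mdd = !records$mdd,
       ptsd = records$group == "ptsd",
       ptsd_mdd = records$group == "ptsd" & records$mdd)
}

run_contrast_stage <- function(dat, covar_cols, metrics_cols) {
  res <- list()
  for (m in metrics_cols) {
    g <- dat$group
    groups <- split(dat[[m]], g)
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) >= 2) {
      an <- one_way_anova(groups, contrast = "all_groups")
      an$method <- paste0("anova_", m)
      res[[length(res) + 1]] <- an
      tr <- trend_test(dat[[m]], g)
      tr$method <- paste0("cuzick_trend_", m)
      res[[length(res) + 1]] <- tr
    }
    pairs <- utils::combn(levels(droplevels(g)), 2, simplify = FALSE)
    for (pr in pairs) {
      x <- dat[[m]][g == pr[2]]; y <- dat[[m]][g == pr[1]]
      if (length(x) < 2 || length(y) < 2) next
      wt <- welch_t(x, y, contrast = paste0(pr[2], "_vs_", pr[1]))
      wt$method <- paste0("welch_", m)
      res[[length(res) + 1]] <- wt
    }
    # PTSD vs all non-PTSD (controls pooled with exposed responders)
    if (sum(dat$group == "ptsd") >= 2 && sum(dat$group != "ptsd") >= 2) {
      wt <- welch_t(dat[[m]][dat$group == "ptsd"],
                    dat[[m]][dat$group != "ptsd"],
                    contrast = "ptsd_vs_all_nonptsd")
      wt$method <- paste0("welch_", m)
      res[[length(res) + 1]] <- wt
    }
    adj <- tryCatch(
      adjusted_group_contrast(dat[[m]], dat$group,
                              dat[, covar_cols, drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(adj)) {
      adj$method <- paste0("adjusted_lm_", m)
      res[[length(res) + 1]] <- adj
    }
  }
  bind_results(res)
}

run_correlation_stage <- function(dat, covar_cols, fdr_alpha = 0.05) {
  subs <- analysis_subgroups(dat)
  out <- list()
  for (sg in names(subs)) {
    sel <- subs[[sg]]
    if (sum(sel) < length(covar_cols) + 4) next
    rows <- list()
    for (dom in symptom_domains()) {
      r <- tryCatch(
        adjusted_spearman(dat$wcpl[sel], dat[[dom]][sel],
                          dat[sel, covar_cols, drop = FALSE],
                          contrast = paste0(sg, ":", dom)),
        error = function(e) NULL)
      if (!is.null(r)) rows[[dom]] <- r
    }
    if (length(rows) == 0) next
    tab <- bind_results(rows)
    fdr <- bh_fdr(tab$p, alpha = fdr_alpha)
    tab$p_adjusted <- fdr$p_adjusted
    tab$fdr_pass <- fdr$rejected
    tab$subgroup <- sg
    out[[sg]] <- tab
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

roc_row <- function(r, label, feature) {
  data.frame(label = label, feature = feature, auc = r$auc,
             ci_low = r$ci_low, ci_high = r$ci_high, n_pos = r$n_pos,
             n_neg = r$n_neg, model = r$model, stringsAsFactors = FALSE)
}

run_roc_stage <- function(dat, covar_cols_roc = c("age", "education",
                                                  "body_mass")) {
  out <- list()
  specs <- list(
    any_ptsd = list(sel = rep(TRUE, nrow(dat)), case = dat$group == "ptsd"),
    ptsd_no_mdd = list(sel = !(dat$group == "ptsd" & dat$mdd),
                       case = dat$group == "ptsd" & !dat$mdd))
  for (nm in names(specs)) {
    sel <- specs[[nm]]$sel
    y <- specs[[nm]]$case[sel]
    if (sum(y) < 2 || sum(!y) < 2) next
    d <- dat[sel, , drop = FALSE]
    out[[length(out) + 1]] <- roc_row(roc_auc(d$wcpl, y), nm, "wcpl")
    if ("cortical_complexity" %in% names(d) &&
        !all(is.na(d$cortical_complexity))) {
      out[[length(out) + 1]] <-
        roc_row(roc_auc(d$cortical_complexity, y), nm,
                "cortical_complexity")
      cs <- combined_score(d[, c("wcpl", "cortical_complexity")], y,
                           d[, covar_cols_roc, drop = FALSE])
      out[[length(out) + 1]] <- roc_row(cs$roc, nm, "combined")
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

run_sensitivity_stage <- function(dat, trim_k = 3, threshold = 80,
                                  covar_cols = c("age", "sex", "education",
                                                 "body_mass")) {
  if (sum(dat$group == "ptsd") <= trim_k) return(NULL)
  analysis <- function(d) {
    res <- list(
      welch_t(d$wcpl[d$group == "ptsd"],
              d$wcpl[d$group == "exposed_noptsd"],
              contrast = "ptsd_vs_exposed_noptsd"),
      welch_t(d$wcpl[d$group == "ptsd"], d$wcpl[d$group != "ptsd"],
              contrast = "ptsd_vs_all_nonptsd"))
    adj <- tryCatch(
      adjusted_group_contrast(d$wcpl, d$group,
                              d[, covar_cols, drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(adj)) res[[length(res) + 1]] <- adj
    bind_results(res)
  }
  sens <- outlier_sensitivity(dat, group = "ptsd", k = trim_k,
                              analysis = analysis, threshold = threshold)
  full <- sens$full; full$sample <- "full"
  trimmed <- sens$trimmed; trimmed$sample <- "trimmed"
  tab <- rbind(full, trimmed)
  attr(tab, "removed_ids") <- sens$removed_ids
  attr(tab, "n_above_threshold") <- sens$n_above_threshold
  attr(tab, "n_above_threshold_in_group") <- sens$n_above_threshold_in_group
  tab
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, computes per-subject global network
#' metrics, and runs the group-contrast, symptom-correlation, ROC and
#' outlier-sensitivity stages, writing one table per stage plus a run
#' manifest under `out_dir`.
#'
#' @param config A [cohort_config()] (used when `cohort` is NULL).
#' @param out_dir Output directory.
#' @param cohort Optional pre-built cohort (as from [generate_cohort()] or
#'   [read_cohort()]); when given, `config` only supplies analysis settings.
#' @param covariate_cols Adjustment covariates for contrasts/correlations.
#' @param swn_mode Small-worldness mode passed to [metrics_for_cohort()].
#' @param trim_k Outlier-sensitivity trim count.
#' @return Invisible list of the stage tables and file paths.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         cohort = NULL,
                         covariate_cols = c("age", "sex", "education",
                                            "body_mass"),
                         swn_mode = "plain", trim_k = 3) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) cohort <- generate_cohort(config)
  metrics <- metrics_for_cohort(cohort, swn_mode = swn_mode,
                                seed = config$seed)
  dat <- merge(cohort$records, metrics, by = "subject_id", sort = TRUE)
  dat$group <- factor(as.character(dat$group), levels = the_group_levels,
                      ordered = TRUE)
  if (is.character(dat$education)) {
    dat$education <- factor(dat$education,
                            levels = c("highschool", "college",
                                       "bachelor_plus"), ordered = TRUE)
  }
  paths <- list(metrics = file.path(out_dir, "metrics.csv"))
  write_results(dat_to_writable(dat), paths$metrics)

  tables <- list(metrics = dat)
  metric_cols <- c("wcpl", "cc", "ge", "swn", "log_swn")
  if (sum(table(dat$group) >= 2) >= 2) {
    tables$contrasts <- run_contrast_stage(dat, covariate_cols, metric_cols)
    paths$contrasts <- file.path(out_dir, "contrasts.csv")
    write_results(tables$contrasts, paths$contrasts)
  } else {
    cp_msg("contrast stage skipped: fewer than two groups with n >= 2")
  }
  tables$correlations <- run_correlation_stage(dat, covariate_cols)
  if (!is.null(tables$correlations)) {
    paths$correlations <- file.path(out_dir, "correlations.csv")
    write_results(tables$correlations, paths$correlations)
  }
  tables$roc <- run_roc_stage(dat)
  if (!is.null(tables$roc)) {
    paths$roc <- file.path(out_dir, "roc.csv")
    write.table(tables$roc, paths$roc, sep = ",", row.names = FALSE,
                quote = FALSE)
  }
  tables$sensitivity <- run_sensitivity_stage(
    dat, trim_k = trim_k, threshold = config$wcpl_report_threshold,
    covar_cols = covariate_cols)
  if (!is.null(tables$sensitivity)) {
    paths$sensitivity <- file.path(out_dir, "sensitivity.csv")
    write_results(tables$sensitivity, paths$sensitivity)
  }
  paths$manifest <- file.path(out_dir, "manifest.json")
  write_manifest(config, paths, out_dir)
  invisible(c(tables, list(paths = paths)))
}

dat_to_writable <- function(dat) {
  out <- dat
  for (nm in names(out)) {
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  out
}

write_manifest <- function(config, paths, out_dir) {
  files <- unlist(paths[names(paths) != "manifest"])
  hashes <- tools::md5sum(files[file.exists(files)])
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("connectopath")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = as.list(setNames(unname(hashes), basename(names(hashes)))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(paths$manifest)
}

fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

#' Render a plain-text summary of a pipeline run
#'
#' Mirrors the conventional reporting structure: group means with SDs,
#' pairwise contrasts with Cohen's d and adjusted p-values, the
#' subgroup-by-domain rank-correlation table with FDR marks, ROC areas with
#' confidence intervals, and the outlier-sensitivity comparison.
#'
#' @param run A list returned by [run_pipeline()] (or a directory containing
#'   its output tables).
#' @return Character vector of markdown lines (also printed invisibly via
#'   `cat` when `print = TRUE`).
#' @param print Whether to `cat` the report.
#' @export
report_run <- function(run, print = TRUE) {
  if (is.character(run)) {
    dirp <- run
    run <- list()
    rd <- function(f) if (file.exists(file.path(dirp, f)))
      read_results(file.path(dirp, f)) else NULL
    run$metrics <- rd("metrics.csv")
    run$contrasts <- rd("contrasts.csv")
    run$correlations <- rd("correlations.csv")
    run$roc <- if (file.exists(file.path(dirp, "roc.csv")))
      read.table(file.path(dirp, "roc.csv"), sep = ",", header = TRUE) else
        NULL
    run$sensitivity <- rd("sensitivity.csv")
  }
  if (is.null(run$metrics)) stop("missing metrics table", call. = FALSE)
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  add("# Connectome path-length analysis")
  add("")
  add("## Group summaries (wCPL)")
  agg <- aggregate(wcpl ~ group, data = run$metrics,
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       n = length(v)))
  for (i in seq_len(nrow(agg))) {
    add(sprintf("- %s: mean %.2f (SD %.2f), n = %d", agg$group[i],
                agg$wcpl[i, "mean"], agg$wcpl[i, "sd"],
                as.integer(agg$wcpl[i, "n"])))
  }
  add("")
  add("## Group contrasts")
  if (is.null(run$contrasts) || nrow(run$contrasts) == 0) {
    add("not computed")
  } else {
    w <- run$contrasts[grepl("^welch_wcpl", run$contrasts$method), ]
    a <- run$contrasts[grepl("^adjusted_lm_wcpl", run$contrasts$method), ]
    for (i in seq_len(nrow(w))) {
      adj_p <- a$p[match(w$contrast[i], a$contrast)]
      add(sprintf("- wCPL %s: d = %.2f, p = %s%s", w$contrast[i],
                  w$effect_size[i], fmt_p(w$p[i]),
                  if (!is.na(adj_p)) paste0(", adjusted p = ", fmt_p(adj_p))
                  else ""))
    }
  }
  add("")
  add("## Symptom correlations (multivariable-adjusted Spearman)")
  if (is.null(run$correlations) || nrow(run$correlations) == 0) {
    add("not computed")
  } else {
    for (i in seq_len(nrow(run$correlations))) {
      r <- run$correlations[i, ]
      add(sprintf("- %s: rho = %.2f, p = %s%s", r$contrast, r$estimate,
                  fmt_p(r$p), if (isTRUE(r$fdr_pass)) " **(passes FDR)**"
                  else ""))
    }
  }
  add("")
  add("## ROC discrimination")
  if (is.null(run$roc) || nrow(run$roc) == 0) {
    add("not computed")
  } else {
    for (i in seq_len(nrow(run$roc))) {
      r <- run$roc[i, ]
      add(sprintf("- %s / %s: AUC = %.2f, 95%% CI [%.2f-%.2f]", r$label,
                  r$feature, r$auc, r$ci_low, r$ci_high))
    }
  }
  add("")
  add("## Outlier sensitivity")
  if (is.null(run$sensitivity) || nrow(run$sensitivity) == 0) {
    add("not computed")
  } else {
    s <- run$sensitivity
    s <- s[grepl("^welch", s$method), ]
    for (i in seq_len(nrow(s))) {
      add(sprintf("- [%s] %s: d = %.2f, p = %s", s$sample[i], s$contrast[i],
                  s$effect_size[i], fmt_p(s$p[i])))
    }
  }
  if (print) cat(paste(L, collapse = "\n"), "\n")
  invisible(L)
}
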