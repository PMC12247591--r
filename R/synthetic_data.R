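# Synthetic connectome cohort generator.
#
# Emulates the study design the analysis assumes: three ordered groups
# (unexposed controls, trauma-exposed responders without PTSD, responders
# with PTSD), MDD comorbidity inside the PTSD group, symptom-checklist
# eligibility bounds, demographic covariates, distance-dependent wiring with
# log-normal tract counts producing a right-skewed path-length distribution,
# a long-range attenuation effect in the PTSD group, and a Gaussian-copula
# link between realized path length and symptom scores.

#' Default cohort configuration
#'
#' Returns the full set of generator knobs. Defaults reproduce the reference
#' study design: 9 controls, 53 exposed responders without PTSD, 47 with
#' PTSD; symptom-domain means/SDs per group; eligibility PCL > 40 for cases
#' and PCL < 30 for non-cases; and a long-range attenuation calibrated so the
#' PTSD+ vs PTSD- path-length difference has Cohen's d near 0.42.
#'
#' @param n_control,n_exposed,n_ptsd Group sizes.
#' @param mdd_rate_in_ptsd Probability of comorbid MDD inside the PTSD group.
#' @param n_nodes Number of ROIs (62 matches the DKT parcellation).
#' @param wiring List: `geometric_decay_rate` (edge-presence decay with
#'   inter-node chord distance on the unit sphere), `base_count_lognormal`
#'   (`c(mu, sigma)` of log tract counts), `subject_sigma` (SD of the
#'   per-subject log-normal scaling factor; drives wCPL skew),
#'   `edge_noise_sigma` (subject-level log-normal edge noise).
#' @param effect List: `long_range_attenuation_ptsd` (above-median-distance
#'   edges in PTSD subjects are multiplied by `1/(1 + attenuation)`),
#'   `target_cohens_d` (informational target the default attenuation was
#'   calibrated to).
#' @param covariates Per-group distributions for age, body mass, sex and
#'   education.
#' @param symptom_model Per-group domain means/SDs and per-subgroup
#'   rank-correlation targets between wCPL and symptoms, keyed by the
#'   disjoint partition `non_ptsd` / `ptsd_no_mdd` / `ptsd_mdd`.
#' @param eligibility PCL bounds: cases above `case_min_pcl`, non-cases below
#'   `noncase_max_pcl`.
#' @param wcpl_report_threshold Reporting cutoff for high-wCPL subjects.
#' @param seed Master integer seed; all randomness fans out from it through
#'   per-subject substreams.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_control = 9, n_exposed = 53, n_ptsd = 47,
                          mdd_rate_in_ptsd = 0.4, n_nodes = 62,
                          wiring = list(geometric_decay_rate = 3,
                                        base_count_lognormal = c(mu = -3.6,
                                                                 sigma = 0.6),
                                        subject_sigma = 0.45,
                                        edge_noise_sigma = 0.2),
                          effect = list(long_range_attenuation_ptsd = 0.5,
                                        target_cohens_d = 0.42),
                          covariates = list(
                            control = list(age = c(52.8, 3.5),
                                           body_mass = c(28.5, 7.9),
                                           p_male = 0.56,
                                           education = c(0.2, 0.3, 0.5)),
                            exposed_noptsd = list(age = c(56.9, 5.3),
                                                  body_mass = c(28.1, 3.6),
                                                  p_male = 0.92,
                                                  education = c(0.3, 0.4, 0.3)),
                            ptsd = list(age = c(55.8, 5.1),
                                        body_mass = c(30.5, 4.1),
                                        p_male = 0.9,
                                        education = c(0.35, 0.4, 0.25))),
                          symptom_model = list(
                            domains = list(
                              re_experiencing = list(
                                control = c(11.7, 3.2),
                                exposed_noptsd = c(12.2, 3.1),
                                ptsd = c(23.4, 4.3)),
                              avoidance = list(
                                control = c(14.7, 1.4),
                                exposed_noptsd = c(16.4, 3.3),
                                ptsd = c(32.7, 6.1)),
                              hyperarousal = list(
                                control = c(10.9, 2.0),
                                exposed_noptsd = c(12.3, 3.2),
                                ptsd = c(24.0, 3.4)),
                              negative_affect = list(
                                control = c(8.0, 0.9),
                                exposed_noptsd = c(9.2, 1.9),
                                ptsd = c(15.8, 4.2))),
                            rho_targets = c(non_ptsd = 0.25,
                                            ptsd_no_mdd = -0.2,
                                            ptsd_mdd = -0.6)),
                          eligibility = list(case_min_pcl = 40,
                                             noncase_max_pcl = 30),
                          wcpl_report_threshold = 80,
                          seed = 1L) {
  cfg <- list(n_control = n_control, n_exposed = n_exposed, n_ptsd = n_ptsd,
              mdd_rate_in_ptsd = mdd_rate_in_ptsd, n_nodes = n_nodes,
              wiring = wiring, effect = effect, covariates = covariates,
              symptom_model = symptom_model, eligibility = eligibility,
              wcpl_report_threshold = wcpl_report_threshold,
              seed = as.integer(seed))
  if (cfg$n_control < 0 || cfg$n_exposed < 0 || cfg$n_ptsd < 0 ||
      cfg$n_control + cfg$n_exposed + cfg$n_ptsd < 2) {
    stop("group sizes must be non-negative with total >= 2", call. = FALSE)
  }
  if (any(abs(cfg$symptom_model$rho_targets) >= 1)) {
    stop("infeasible correlation target: |rho| must be < 1", call. = FALSE)
  }
  if (cfg$effect$long_range_attenuation_ptsd < 0) {
    stop("attenuation must be >= 0", call. = FALSE)
  }
  class(cfg) <- "cohort_config"
  cfg
}

# near-uniform deterministic-ish layout: random points on the unit sphere
sphere_layout <- function(n) {
  z <- matrix(rnorm(3 * n), ncol = 3)
  z / sqrt(rowSums(z^2))
}

# rank-based normal scores (Blom), robust to ties
rank_normal <- function(x) {
  n <- length(x)
  qnorm((rank(x, ties.method = "average") - 0.375) / (n + 0.25))
}

#' Generate a synthetic connectome cohort
#'
#' Builds a shared anatomy (node layout on the unit sphere, a
#' distance-decaying edge backbone augmented to be connected, and log-normal
#' base tract counts), then per-subject matrices as the backbone scaled by a
#' subject-level log-normal factor plus edge noise. Subjects in the PTSD
#' group have their long-range edges (above-median inter-node distance)
#' attenuated, which raises their characteristic path length. Symptom scores
#' are then drawn by a Gaussian copula on the realized wCPL ranks so that
#' configured subgroup rank correlations hold, and the PCL eligibility filter
#' is applied.
#'
#' @param config A [cohort_config()].
#' @return A `cohort` list: `records` (metadata data.frame including realized
#'   subgroup), `matrices` (named list of `connectivity_matrix`), `config`,
#'   and `log` (eligibility filter counts).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_rng <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng,
                                        envir = globalenv()))

  ng <- c(control = config$n_control, exposed_noptsd = config$n_exposed,
          ptsd = config$n_ptsd)
  group <- factor(rep(names(ng), ng), levels = the_group_levels,
                  ordered = TRUE)
  n_sub <- length(group)
  ids <- sprintf("S%04d", seq_len(n_sub))

  # --- shared anatomy (one substream) ---
  set.seed(substream_seed(config$seed, 0L))
  xyz <- sphere_layout(config$n_nodes)
  d_geo <- as.matrix(stats::dist(xyz))
  lam <- config$wiring$geometric_decay_rate
  p_edge <- exp(-lam * d_geo / max(d_geo))
  upper <- upper.tri(d_geo)
  present <- matrix(FALSE, config$n_nodes, config$n_nodes)
  present[upper] <- runif(sum(upper)) < p_edge[upper]
  present <- present | t(present)
  # guarantee connectivity via a ring over a random node order
  ord <- sample.int(config$n_nodes)
  for (i in seq_len(config$n_nodes)) {
    a <- ord[i]; b <- ord[if (i == config$n_nodes) 1L else i + 1L]
    present[a, b] <- present[b, a] <- TRUE
  }
  diag(present) <- FALSE
  mu <- config$wiring$base_count_lognormal[["mu"]]
  sig <- config$wiring$base_count_lognormal[["sigma"]]
  base <- matrix(0, config$n_nodes, config$n_nodes)
  base[upper] <- rlnorm(sum(upper), meanlog = mu, sdlog = sig)
  base <- base + t(base)
  base[!present] <- 0
  med_d <- median(d_geo[upper][present[upper]])
  long_range <- present & (d_geo > med_d)

  # --- per-subject matrices (substreams 1..n) ---
  att <- config$effect$long_range_attenuation_ptsd
  s_sig <- config$wiring$subject_sigma
  e_sig <- config$wiring$edge_noise_sigma
  matrices <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    set.seed(substream_seed(config$seed, i))
    s_i <- rlnorm(1, meanlog = 0, sdlog = s_sig)
    noise <- matrix(0, config$n_nodes, config$n_nodes)
    noise[upper] <- rlnorm(sum(upper), meanlog = 0, sdlog = e_sig)
    noise <- noise + t(noise)
    w <- base * s_i * noise
    if (group[i] == "ptsd" && att > 0) {
      w[long_range] <- w[long_range] / (1 + att)
    }
    matrices[[i]] <- connectivity_matrix(w)
  }
  names(matrices) <- ids

  # --- covariates + MDD (substreams n+1..2n) ---
  cov_rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    set.seed(substream_seed(config$seed, n_sub + i))
    gc <- config$covariates[[as.character(group[i])]]
    mdd <- group[i] == "ptsd" && runif(1) < config$mdd_rate_in_ptsd
    edu <- sample(c("highschool", "college", "bachelor_plus"), 1,
                  prob = gc$education)
    cov_rows[[i]] <- data.frame(
      subject_id = ids[i], group = as.character(group[i]), mdd = mdd,
      age = rnorm(1, gc$age[1], gc$age[2]),
      sex = if (runif(1) < gc$p_male) "male" else "female",
      education = edu,
      body_mass = rnorm(1, gc$body_mass[1], gc$body_mass[2]),
      dementia = FALSE, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, cov_rows)
  rec$group <- factor(rec$group, levels = the_group_levels, ordered = TRUE)
  rec$education <- factor(rec$education,
                          levels = c("highschool", "college",
                                     "bachelor_plus"), ordered = TRUE)

  # --- realized wCPL and symptom copula (one substream) ---
  wcpl_i <- vapply(matrices, function(m) {
    wcpl(shortest_paths_all(to_distance(m)))$wcpl
  }, 0)
  subgroup <- ifelse(rec$group != "ptsd", "non_ptsd",
                     ifelse(rec$mdd, "ptsd_mdd", "ptsd_no_mdd"))
  rec$subgroup <- subgroup
  set.seed(substream_seed(config$seed, 2L * n_sub + 1L))
  zw <- numeric(n_sub)
  for (sg in unique(subgroup)) {
    sel <- subgroup == sg
    zw[sel] <- if (sum(sel) > 1) rank_normal(wcpl_i[sel]) else 0
  }
  rho <- config$symptom_model$rho_targets
  rho_i <- rho[subgroup]
  for (dom in names(config$symptom_model$domains)) {
    par <- config$symptom_model$domains[[dom]]
    eps <- rnorm(n_sub)
    zsym <- rho_i * zw + sqrt(1 - rho_i^2) * eps
    mu_g <- vapply(as.character(rec$group), function(g) par[[g]][1], 0)
    sd_g <- vapply(as.character(rec$group), function(g) par[[g]][2], 0)
    rec[[dom]] <- pmax(0, mu_g + sd_g * zsym)
  }
  rec$overall <- rec$re_experiencing + rec$avoidance + rec$hyperarousal +
    rec$negative_affect

  # PCL instrument total, constructed to satisfy the eligibility design
  is_case <- rec$group == "ptsd"
  rec$pcl_total <- ifelse(
    is_case,
    config$eligibility$case_min_pcl + 1 + abs(rnorm(n_sub, 10, 6)),
    pmax(17, config$eligibility$noncase_max_pcl - 1 - abs(rnorm(n_sub, 5, 3))))

  # cortical complexity: mildly PTSD-shifted, rank-uncorrelated with wCPL
  rec$cortical_complexity <- rnorm(n_sub) + 0.55 * as.numeric(is_case)

  # --- eligibility filter ---
  keep <- ifelse(is_case, rec$pcl_total > config$eligibility$case_min_pcl,
                 rec$pcl_total < config$eligibility$noncase_max_pcl)
  n_filtered <- sum(!keep)
  if (n_filtered > 0) {
    cp_msg("eligibility filter removed ", n_filtered, " subject(s)")
  }
  rec <- rec[keep, , drop = FALSE]
  matrices <- matrices[rec$subject_id]
  rownames(rec) <- NULL

  structure(list(records = rec, matrices = matrices, config = config,
                 log = list(n_filtered = n_filtered)),
            class = "cohort")
}

realized_cohens_d <- function(config) {
  cohort <- generate_cohort(config)
  met <- vapply(cohort$matrices, function(m) {
    wcpl(shortest_paths_all(to_distance(m)))$wcpl
  }, 0)
  g <- cohort$records$group
  x <- met[g == "ptsd"]; y <- met[g == "exposed_noptsd"]
  cohens_d(x, y)
}

#' Calibrate the long-range attenuation to a target effect size
#'
#' Monotone bisection on the attenuation knob until the mean realized
#' Cohen's d (PTSD vs exposed-no-PTSD wCPL, pooled-SD convention) across
#' `n_rep` simulated cohorts is within `tol` of `target_d`.
#'
#' @param config A [cohort_config()] (its attenuation value is ignored).
#' @param target_d Target Cohen's d (>= 0).
#' @param n_rep Cohorts per evaluation.
#' @param tol Convergence tolerance on the mean d.
#' @param max_iter Bisection iteration cap.
#' @return List: `attenuation`, `achieved_d`.
#' @export
calibrate_attenuation <- function(config = cohort_config(), target_d,
                                  n_rep = 8, tol = 0.05, max_iter = 12) {
  stopifnot(target_d >= 0)
  eval_d <- function(att) {
    mean(vapply(seq_len(n_rep), function(r) {
      cfg <- config
      cfg$effect$long_range_attenuation_ptsd <- att
      cfg$seed <- substream_seed(config$seed, 10000L + r)
      realized_cohens_d(cfg)
    }, 0))
  }
  d0 <- eval_d(0)
  if (abs(d0 - target_d) <= tol) {
    return(list(attenuation = 0, achieved_d = d0))
  }
  hi <- 0.5
  d_hi <- eval_d(hi)
  while (d_hi < target_d && hi < 16) {
    hi <- hi * 2
    d_hi <- eval_d(hi)
  }
  if (d_hi < target_d) {
    stop("target effect size unreachable at attenuation <= 16", call. = FALSE)
  }
  lo <- 0; d_cur <- d_hi; att <- hi
  for (it in seq_len(max_iter)) {
    att <- (lo + hi) / 2
    d_cur <- eval_d(att)
    if (abs(d_cur - target_d) <= tol) break
    if (d_cur < target_d) lo <- att else hi <- att
  }
  list(attenuation = att, achieved_d = d_cur)
}

#' Write a cohort to disk
#'
#' One connectivity-matrix file per subject under `dir/matrices/` plus a
#' `metadata.csv`, in the formats the readers accept.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisible list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  mpaths <- vapply(cohort$records$subject_id, function(id) {
    p <- file.path(mdir, paste0(id, ".csv"))
    write_matrix(cohort$matrices[[id]], p)
    p
  }, "")
  meta <- file.path(dir, "metadata.csv")
  write_metadata(cohort$records, meta)
  invisible(list(metadata = meta, matrices = mpaths))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `metadata.csv` and `matrices/`.
#' @return A `cohort` list (without generator config).
#' @export
read_cohort <- function(dir) {
  rec <- read_metadata(file.path(dir, "metadata.csv"))
  matrices <- lapply(rec$subject_id, function(id) {
    read_matrix(file.path(dir, "matrices", paste0(id, ".csv")))
  })
  names(matrices) <- rec$subject_id
  structure(list(records = rec, matrices = matrices), class = "cohort")
}
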