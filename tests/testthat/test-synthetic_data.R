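test_that("cohort generation is fully reproducible from its seed", {
  cfg <- small_cohort_config(seed = 12)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(lapply(c1$matrices, unclass),
                   lapply(c2$matrices, unclass))
  c3 <- generate_cohort(small_cohort_config(seed = 13))
  expect_false(identical(c1$records$age, c3$records$age))
})

test_that("config validation rejects infeasible settings", {
  expect_error(cohort_config(n_control = -1), "non-negative")
  expect_error(cohort_config(n_control = 1, n_exposed = 0, n_ptsd = 0),
               "total >= 2")
  sm <- cohort_config()$symptom_model
  sm$rho_targets["ptsd_mdd"] <- -1
  expect_error(cohort_config(symptom_model = sm), "infeasible correlation")
  eff <- cohort_config()$effect
  eff$long_range_attenuation_ptsd <- -0.2
  expect_error(cohort_config(effect = eff), "attenuation")
})

test_that("groups, MDD placement and eligibility follow the design", {
  cohort <- generate_cohort(small_cohort_config(seed = 2))
  rec <- cohort$records
  expect_true(all(!rec$mdd[rec$group != "ptsd"]))
  is_case <- rec$group == "ptsd"
  expect_true(all(rec$pcl_total[is_case] > 40))
  expect_true(all(rec$pcl_total[!is_case] < 30))
  expect_true(all(rec$re_experiencing >= 0))
  expect_true(all(rec$overall >= 0))
  # zero-size group simply drops out
  cohort0 <- generate_cohort(small_cohort_config(n_control = 0, seed = 2))
  expect_equal(sort(unique(as.character(cohort0$records$group))),
               c("exposed_noptsd", "ptsd"))
})

test_that("attenuation of zero produces no group difference in wcpl", {
  ds <- vapply(1:12, function(s) {
    cfg <- cohort_config(n_control = 0, n_exposed = 40, n_ptsd = 40,
                         n_nodes = 20, seed = s)
    cfg$effect$long_range_attenuation_ptsd <- 0
    co <- generate_cohort(cfg)
    w <- vapply(co$matrices, function(m) {
      wcpl(shortest_paths_all(to_distance(m)))$wcpl
    }, 0)
    g <- co$records$group
    cohens_d(w[g == "ptsd"], w[g == "exposed_noptsd"])
  }, 0)
  expect_lt(abs(mean(ds)), 0.1)
})

test_that("realized effect size is monotone in the attenuation knob", {
  d_at <- function(att) {
    mean(vapply(1:6, function(s) {
      cfg <- cohort_config(n_control = 0, n_exposed = 40, n_ptsd = 40,
                           n_nodes = 20, seed = s)
      cfg$effect$long_range_attenuation_ptsd <- att
      co <- generate_cohort(cfg)
      w <- vapply(co$matrices, function(m) {
        wcpl(shortest_paths_all(to_distance(m)))$wcpl
      }, 0)
      g <- co$records$group
      cohens_d(w[g == "ptsd"], w[g == "exposed_noptsd"])
    }, 0))
  }
  ds <- vapply(c(0, 1, 4), d_at, 0)
  expect_true(all(diff(ds) > 0))
})

test_that("calibration maps a null target to a null knob", {
  cfg <- cohort_config(n_control = 0, n_exposed = 25, n_ptsd = 25,
                       n_nodes = 16, seed = 5)
  cal <- calibrate_attenuation(cfg, target_d = 0, n_rep = 3, tol = 0.15)
  expect_equal(cal$attenuation, 0)
  expect_lt(abs(cal$achieved_d), 0.15)
})

test_that("wcpl distribution is right-skewed under study-design defaults", {
  skews <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(seed = s))
    w <- vapply(co$matrices, function(m) {
      wcpl(shortest_paths_all(to_distance(m)))$wcpl
    }, 0)
    distribution_diagnostics(w)$skew
  }, 0)
  expect_gte(sum(skews > 0.5), 3)
})

test_that("copula hits subgroup rank-correlation targets at n >= 200", {
  cfg <- cohort_config(n_control = 0, n_exposed = 200, n_ptsd = 220,
                       mdd_rate_in_ptsd = 0, n_nodes = 20, seed = 8)
  cfg$symptom_model$rho_targets <- c(non_ptsd = 0.3, ptsd_no_mdd = -0.5,
                                     ptsd_mdd = -0.6)
  co <- generate_cohort(cfg)
  met <- vapply(co$matrices, function(m) {
    wcpl(shortest_paths_all(to_distance(m)))$wcpl
  }, 0)
  rec <- co$records
  for (sg in c("non_ptsd", "ptsd_no_mdd")) {
    sel <- rec$subgroup == sg
    rho <- cor(met[sel], rec$avoidance[sel], method = "spearman")
    expect_lt(abs(rho - cfg$symptom_model$rho_targets[[sg]]), 0.1)
    # marginal moments preserved within Monte-Carlo error
    grp <- as.character(rec$group[sel][1])
    par <- cfg$symptom_model$domains$avoidance[[grp]]
    expect_lt(abs(mean(rec$avoidance[sel]) - par[1]),
              4 * par[2] / sqrt(sum(sel)))
    expect_lt(abs(sd(rec$avoidance[sel]) - par[2]) / par[2], 0.15)
  }
})

test_that("written cohorts read back with identical metrics", {
  cohort <- generate_cohort(small_cohort_config(seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_length(list.files(file.path(dir, "matrices")),
                nrow(cohort$records))
  back <- read_cohort(dir)
  m1 <- metrics_for_cohort(cohort)
  m2 <- metrics_for_cohort(back)
  expect_equal(m1$wcpl, m2$wcpl, tolerance = 1e-9)
  expect_equal(m1$cc, m2$cc, tolerance = 1e-9)
})
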