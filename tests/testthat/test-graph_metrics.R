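test_that("distance matrix is the reciprocal of the tract counts", {
  conn <- triangle_conn(ab = 4, bc = 2, ac = 0)
  d <- to_distance(conn)
  expect_equal(d["A", "B"], 0.25)
  expect_equal(d["B", "C"], 0.5)
  expect_equal(d["A", "C"], Inf)
  expect_equal(diag(unclass(d)), c(A = 0, B = 0, C = 0))
  # homogeneity: scaling counts by c scales finite distances by 1/c
  d2 <- to_distance(connectivity_matrix(unclass(conn) * 5,
                                        nodes = rownames(conn)))
  fin <- is.finite(d) & upper.tri(d)
  expect_equal(unclass(d2)[fin], unclass(d)[fin] / 5, tolerance = 1e-12)
})

test_that("shortest paths handle chains and two-hop detours", {
  sp <- shortest_paths_all(to_distance(chain_conn()))
  expect_equal(sp["A", "B"], 0.5)
  expect_equal(sp["B", "C"], 0.25)
  expect_equal(sp["A", "C"], 0.75)
  # detour through B (0.1 + 0.1) beats the direct edge (1.0)
  sp2 <- shortest_paths_all(to_distance(triangle_conn(10, 10, 1)))
  expect_equal(sp2["A", "C"], 0.2)
})

test_that("Dijkstra agrees with the Floyd-Warshall oracle on random graphs", {
  for (s in 1:200) {
    n <- 4 + (s %% 9)  # 4..12 nodes
    conn <- random_conn(n, density = 0.3 + (s %% 5) / 10, seed = s)
    d <- to_distance(conn)
    sp <- shortest_paths_all(d)
    expect_equal(unclass(sp), fw_oracle(d), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("wcpl and global efficiency match hand-computed values", {
  # complete graph, uniform count 2: every distance 0.5
  comp <- connectivity_matrix(matrix(2, 4, 4) - diag(2, 4))
  sp <- shortest_paths_all(to_distance(comp))
  expect_equal(wcpl(sp)$wcpl, 0.5)
  expect_equal(global_efficiency(sp), 2)

  sp_chain <- shortest_paths_all(to_distance(chain_conn()))
  expect_equal(wcpl(sp_chain)$wcpl, 0.5)

  sp_tri <- shortest_paths_all(to_distance(triangle_conn(10, 10, 1)))
  expect_equal(wcpl(sp_tri)$wcpl, (0.1 + 0.1 + 0.2) / 3)
  expect_equal(global_efficiency(sp_tri), (10 + 10 + 5) / 3)
})

test_that("disconnected pairs are excluded and counted, empty is an error", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 2
  w[3, 4] <- w[4, 3] <- 4
  sp <- shortest_paths_all(to_distance(connectivity_matrix(w)))
  res <- wcpl(sp)
  expect_equal(res$wcpl, mean(c(0.5, 0.25)))
  expect_equal(res$n_disconnected_pairs, 4)
  # two isolated nodes
  sp0 <- shortest_paths_all(to_distance(
    connectivity_matrix(matrix(0, 2, 2))))
  expect_equal(global_efficiency(sp0), 0)
  expect_error(wcpl(sp0), "empty network")
})

test_that("clustering coefficient matches closed forms and is scale-free", {
  tri <- connectivity_matrix(matrix(3, 3, 3) - diag(3, 3))
  expect_equal(clustering_coefficient(tri), 1)
  expect_equal(clustering_coefficient(chain_conn()), 0)
  conn <- random_connected_conn(12, seed = 5)
  cc1 <- clustering_coefficient(conn)
  cc2 <- clustering_coefficient(
    connectivity_matrix(unclass(conn) * 7.3, nodes = rownames(conn)))
  expect_equal(cc1, cc2, tolerance = 1e-12)
  expect_gte(cc1, 0)
  expect_lte(cc1, 1)
})

test_that("small-worldness ratio and self-normalization behave", {
  expect_equal(small_worldness(1, 0.5, mode = "plain"), 2)
  conn <- random_connected_conn(10, seed = 3)
  m <- subject_metrics(conn)
  expect_equal(small_worldness(m$cc, m$wcpl, mode = "normalized",
                               null_ensemble = list(conn)), 1,
               tolerance = 1e-12)
  expect_error(small_worldness(1, 0), "wcpl > 0")
  expect_error(small_worldness(1, 1, mode = "normalized",
                               null_ensemble = list()), "ensemble")
})

test_that("rewired nulls keep the degree sequence and weight multiset", {
  base <- ring_lattice_conn(30, 4)
  # heterogeneous weights so the multiset check is informative
  w <- unclass(base)
  set.seed(11)
  up <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  w[up] <- runif(nrow(up), 1, 10)
  w[lower.tri(w)] <- 0
  w <- w + t(w)
  conn <- connectivity_matrix(w)
  null1 <- rewire_null(conn, n_swaps = 600, seed = 99)
  null2 <- rewire_null(conn, n_swaps = 600, seed = 99)
  expect_identical(unclass(null1), unclass(null2))
  expect_equal(rowSums(unclass(null1) > 0), rowSums(unclass(conn) > 0))
  expect_equal(sort(null1[upper.tri(null1) & null1 > 0]),
               sort(conn[upper.tri(conn) & conn > 0]), tolerance = 1e-12)
  expect_false(identical(unclass(null1), unclass(conn)))
  # complete graph admits no swap
  comp <- connectivity_matrix(matrix(1, 4, 4) - diag(4))
  expect_warning(out <- rewire_null(comp, 10, seed = 1), "no legal swap")
  expect_equal(unclass(out), unclass(comp))
})

test_that("rewiring destroys lattice triangles in nearly all seeds", {
  conn <- ring_lattice_conn(30, 4)
  tri_count <- function(m) {
    a <- unclass(m) > 0
    sum(diag(a %*% a %*% a)) / 6
  }
  t0 <- tri_count(conn)
  decreased <- vapply(1:100, function(s) {
    tri_count(rewire_null(conn, n_swaps = 100 * 60, seed = s)) < t0
  }, TRUE)
  expect_gte(sum(decreased), 95)
})

test_that("lattice-like graphs have normalized small-worldness above 1", {
  conn <- ring_lattice_conn(30, 4)
  m <- subject_metrics(conn)
  nulls <- lapply(1:20, function(s) rewire_null(conn, 100 * 60, seed = s))
  sigma <- small_worldness(m$cc, m$wcpl, mode = "normalized",
                           null_ensemble = nulls)
  expect_gt(sigma, 1)
})

test_that("cohort metrics are deterministic and carry subject context", {
  cohort <- generate_cohort(small_cohort_config(seed = 4))
  m1 <- metrics_for_cohort(cohort)
  m2 <- metrics_for_cohort(cohort)
  expect_identical(m1, m2)
  expect_named(m1, c("subject_id", "wcpl", "cc", "ge", "swn", "log_swn",
                     "n_disconnected_pairs"))
  expect_equal(nrow(m1), nrow(cohort$records))
  expect_true(all(m1$ge >= 1 / m1$wcpl - 1e-12))
  # missing matrix raises with subject id
  broken <- cohort
  broken$matrices[[cohort$records$subject_id[3]]] <- NULL
  expect_error(metrics_for_cohort(broken), cohort$records$subject_id[3])
})
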