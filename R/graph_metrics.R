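# Distance-matrix construction and global network measures.
#
# Tract counts are connection strengths; edge length is their reciprocal, so
# strongly connected region pairs are "close". All global measures operate on
# the resulting weighted graph.

#' Convert tract counts to an edge-length (distance) matrix
#'
#' Edge length is the reciprocal of the tract count: `d_ij = 1 / w_ij` where
#' tracts exist, `Inf` where none do, and 0 on the diagonal.
#'
#' @param conn A `connectivity_matrix`.
#' @return A `distance_matrix`: numeric matrix with the same node labels.
#' @export
to_distance <- function(conn) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  d <- ifelse(conn > 0, 1 / unclass(conn), Inf)
  diag(d) <- 0
  dimnames(d) <- dimnames(conn)
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

dist_to_igraph <- function(dist) {
  adj <- dist
  adj[!is.finite(adj)] <- 0
  diag(adj) <- 0
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE)
}

#' All-pairs weighted shortest path lengths
#'
#' Dijkstra's algorithm from every source over the distance matrix; absent
#' edges (`Inf`) are non-traversable and disconnected pairs keep `Inf`.
#'
#' @param dist A `distance_matrix` from [to_distance()].
#' @return A `path_length_matrix`: symmetric matrix of shortest-path
#'   distances with zero diagonal.
#' @export
shortest_paths_all <- function(dist) {
  stopifnot(inherits(dist, "distance_matrix"))
  g <- dist_to_igraph(dist)
  sp <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(sp) <- dimnames(dist)
  structure(sp, class = c("path_length_matrix", "matrix", "array"))
}

#' Weighted characteristic path length
#'
#' The average shortest path length over unordered node pairs. Disconnected
#' pairs (infinite distance) are excluded from the average and counted; an
#' entirely disconnected network is an error.
#'
#' @param splen A `path_length_matrix`.
#' @return List with `wcpl` (the mean) and `n_disconnected_pairs`.
#' @export
wcpl <- function(splen) {
  stopifnot(inherits(splen, "path_length_matrix"))
  v <- splen[upper.tri(splen)]
  fin <- is.finite(v)
  if (!any(fin)) stop("empty network: all node pairs disconnected",
                      call. = FALSE)
  n_disc <- sum(!fin)
  if (n_disc > 0) {
    cp_msg("wcpl: excluding ", n_disc, " disconnected pair(s) from average")
  }
  list(wcpl = mean(v[fin]), n_disconnected_pairs = n_disc)
}

#' Global efficiency
#'
#' Mean over unordered node pairs of the inverse shortest path length, with
#' disconnected pairs contributing zero. Dominated by short paths where the
#' characteristic path length is dominated by long ones.
#'
#' @param splen A `path_length_matrix`.
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(splen) {
  stopifnot(inherits(splen, "path_length_matrix"))
  v <- splen[upper.tri(splen)]
  mean(ifelse(is.finite(v) & v > 0, 1 / v, 0))
}

#' Weighted clustering coefficient
#'
#' Mean over nodes of the geometric-mean-of-triangle-weights clustering
#' coefficient, with weights normalized by the global maximum weight
#' (Onnela form). Nodes with binary degree < 2 contribute 0.
#'
#' @param conn A `connectivity_matrix`.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(conn) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  w <- unclass(conn)
  wmax <- max(w)
  if (wmax == 0) return(0)
  wn <- (w / wmax)^(1 / 3)
  tri <- diag(wn %*% wn %*% wn)        # 2x geometric-mean triangle intensity
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Small-worldness
#'
#' Plain mode is the ratio of the clustering coefficient to the weighted
#' characteristic path length. Normalized mode divides each component by its
#' mean over a degree-preserving rewired null ensemble, giving the
#' conventional scale-free sigma.
#'
#' @param cc Clustering coefficient of the graph.
#' @param wcpl_value Weighted characteristic path length of the graph.
#' @param mode `"plain"` or `"normalized"`.
#' @param null_ensemble For `mode = "normalized"`, a list of
#'   `connectivity_matrix` null networks (see [rewire_null()]).
#' @return Scalar small-worldness.
#' @export
small_worldness <- function(cc, wcpl_value, mode = c("plain", "normalized"),
                            null_ensemble = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(wcpl_value) || wcpl_value <= 0) {
    stop("small_worldness requires wcpl > 0", call. = FALSE)
  }
  if (mode == "plain") return(cc / wcpl_value)
  if (length(null_ensemble) == 0) {
    stop("normalized mode requires a non-empty null ensemble", call. = FALSE)
  }
  null_stats <- vapply(null_ensemble, function(m) {
    sp <- shortest_paths_all(to_distance(m))
    c(cc = clustering_coefficient(m), wcpl = wcpl(sp)$wcpl)
  }, c(cc = 0, wcpl = 0))
  (cc / mean(null_stats["cc", ])) / (wcpl_value / mean(null_stats["wcpl", ]))
}

#' Degree-preserving rewired null network
#'
#' Randomizes topology by repeated double-edge swaps: edges (a,b), (c,d)
#' become (a,c), (b,d) (or (a,d), (b,c)) when all four nodes are distinct and
#' the new edges do not already exist. Each edge carries its weight through
#' the swap, so the binary degree sequence and the weight multiset are both
#' preserved exactly.
#'
#' @param conn A `connectivity_matrix`.
#' @param n_swaps Number of attempted swaps (commonly 10-100 times the edge
#'   count).
#' @param seed Integer seed; same seed gives an identical null.
#' @return A rewired `connectivity_matrix`. If no legal swap exists (graphs
#'   too small or complete) the input is returned with a warning.
#' @export
rewire_null <- function(conn, n_swaps, seed) {
  stopifnot(inherits(conn, "connectivity_matrix"), n_swaps >= 1)
  n <- nrow(conn)
  idx <- which(upper.tri(conn) & conn > 0, arr.ind = TRUE)
  m <- nrow(idx)
  if (n < 4 || m < 2 || m == n * (n - 1) / 2) {
    warning("no legal swap possible; returning input unchanged")
    return(conn)
  }
  edges <- cbind(idx[, 1], idx[, 2])
  wts <- conn[idx]
  present <- unclass(conn) > 0
  old_rng <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng,
                                        envir = globalenv()))
  set.seed(seed)
  successes <- 0L
  for (s in seq_len(n_swaps)) {
    pick <- sample.int(m, 2L)
    e1 <- edges[pick[1], ]; e2 <- edges[pick[2], ]
    if (runif(1) < 0.5) e2 <- rev(e2)
    a <- e1[1]; b <- e1[2]; c_ <- e2[1]; d <- e2[2]
    if (length(unique(c(a, b, c_, d))) < 4) next
    if (present[a, c_] || present[b, d]) next
    present[a, b] <- present[b, a] <- FALSE
    present[c_, d] <- present[d, c_] <- FALSE
    present[a, c_] <- present[c_, a] <- TRUE
    present[b, d] <- present[d, b] <- TRUE
    edges[pick[1], ] <- sort(c(a, c_))
    edges[pick[2], ] <- sort(c(b, d))
    successes <- successes + 1L
  }
  if (successes == 0L) {
    warning("no legal swap found in ", n_swaps, " attempts; returning input")
    return(conn)
  }
  out <- matrix(0, n, n)
  out[edges] <- wts
  out <- out + t(out)
  connectivity_matrix(out, nodes = rownames(conn))
}

#' Global network metrics for one subject
#'
#' @param conn A `connectivity_matrix`.
#' @param swn_mode `"plain"` or `"normalized"` small-worldness.
#' @param n_nulls,seed Null-ensemble size and seed for normalized
#'   small-worldness.
#' @return One-row data.frame: `wcpl`, `cc`, `ge`, `swn`, `log_swn`,
#'   `n_disconnected_pairs`.
#' @export
subject_metrics <- function(conn, swn_mode = "plain", n_nulls = 20,
                            seed = 1L) {
  sp <- shortest_paths_all(to_distance(conn))
  w <- wcpl(sp)
  cc <- clustering_coefficient(conn)
  ge <- global_efficiency(sp)
  nulls <- NULL
  if (swn_mode == "normalized") {
    nulls <- lapply(seq_len(n_nulls), function(i) {
      rewire_null(conn, n_swaps = 20L * sum(conn[upper.tri(conn)] > 0),
                  seed = substream_seed(seed, i))
    })
  }
  swn <- small_worldness(cc, w$wcpl, mode = swn_mode, null_ensemble = nulls)
  if (swn <= 0) stop("cannot log-transform non-positive small-worldness",
                     call. = FALSE)
  data.frame(wcpl = w$wcpl, cc = cc, ge = ge, swn = swn, log_swn = log(swn),
             n_disconnected_pairs = w$n_disconnected_pairs)
}

#' Global network metrics for every subject in a cohort
#'
#' @param cohort A cohort list with `records` (metadata data.frame) and
#'   `matrices` (named list of `connectivity_matrix`, keyed by subject id).
#' @param swn_mode,n_nulls,seed Passed to [subject_metrics()].
#' @return Data.frame with one row per subject (`subject_id` first column).
#' @export
metrics_for_cohort <- function(cohort, swn_mode = "plain", n_nulls = 20,
                               seed = 1L) {
  ids <- cohort$records$subject_id
  missing_ids <- setdiff(ids, names(cohort$matrices))
  if (length(missing_ids) > 0) {
    stop("no matrix for subject ", missing_ids[1], call. = FALSE)
  }
  node_sets <- unique(lapply(cohort$matrices[ids], rownames))
  if (length(node_sets) > 1) {
    stop("matrices do not share a common node set", call. = FALSE)
  }
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    row <- tryCatch(
      subject_metrics(cohort$matrices[[id]], swn_mode = swn_mode,
                      n_nulls = n_nulls, seed = substream_seed(seed, i)),
      error = function(e) stop("subject ", id, ": ", conditionMessage(e),
                               call. = FALSE))
    cbind(data.frame(subject_id = id, stringsAsFactors = FALSE), row)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
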