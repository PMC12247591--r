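options(connectopath.quiet = TRUE)

# Independent all-pairs shortest-path oracle: Floyd-Warshall on the distance
# matrix, written without reference to the package's Dijkstra path.
fw_oracle <- function(d) {
  n <- nrow(d)
  sp <- unclass(d)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      via <- sp[i, k] + sp[k, ]
      shorter <- via < sp[i, ]
      sp[i, shorter] <- via[shorter]
    }
  }
  sp
}

# random symmetric tract-count matrix, weights U(wmin, wmax), edges kept
# with probability `density`
random_conn <- function(n, density = 0.6, seed = 1, wmin = 1, wmax = 10) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- runif(sum(up), wmin, wmax)
  vals[runif(sum(up)) > density] <- 0
  w[up] <- vals
  w <- w + t(w)
  connectivity_matrix(w)
}

# random connected tract-count matrix (random edges + ring backbone)
random_connected_conn <- function(n, density = 0.4, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- which(upper.tri(w), arr.ind = TRUE)
  keep <- runif(nrow(up)) < density
  w[up[keep, , drop = FALSE]] <- runif(sum(keep), 1, 10)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- min(i, j); b <- max(i, j)
    if (w[a, b] == 0) w[a, b] <- runif(1, 1, 10)
  }
  w[lower.tri(w)] <- 0
  w <- w + t(w)
  connectivity_matrix(w)
}

# ring lattice: each node connected to its k nearest neighbours (k even)
ring_lattice_conn <- function(n, k, weight = 2) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k / 2)) {
      j <- ((i - 1 + s) %% n) + 1
      w[i, j] <- w[j, i] <- weight
    }
  }
  connectivity_matrix(w)
}

triangle_conn <- function(ab = 10, bc = 10, ac = 1) {
  connectivity_matrix(matrix(c(0, ab, ac, ab, 0, bc, ac, bc, 0), 3, 3),
                      nodes = c("A", "B", "C"))
}

chain_conn <- function() {
  connectivity_matrix(matrix(c(0, 2, 0, 2, 0, 4, 0, 4, 0), 3, 3),
                      nodes = c("A", "B", "C"))
}

small_cohort_config <- function(seed = 1, n_control = 4, n_exposed = 12,
                                n_ptsd = 12, n_nodes = 20) {
  cohort_config(n_control = n_control, n_exposed = n_exposed,
                n_ptsd = n_ptsd, n_nodes = n_nodes, seed = seed)
}
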