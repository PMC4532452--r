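# Fixtures are built in code at test time; nothing is read from disk except
# in the I/O round-trip tests, which write to tempfiles.

# Deterministic wiggly 3D chain, independent of the package's own generator
# (used as ground truth where the generator itself is under test elsewhere).
fixture_chain <- function(n, scale = 100) {
  t <- seq_len(n)
  cbind(scale * cos(t / 3) + 0.5 * t,
        scale * sin(t / 3) + 0.2 * t,
        0.8 * scale * sin(t / 7) + 0.1 * t)
}

# Random symmetric matrix with zero diagonal.
rand_sym <- function(n, zero_diag = TRUE) {
  m <- matrix(rnorm(n * n), n)
  m <- (m + t(m)) / 2
  if (zero_diag) diag(m) <- 0
  m
}

# Sparse random contact map over n bins (plus implicit backbone downstream).
rand_cmap <- function(n, n_contacts, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  idx <- which(upper.tri(m) & abs(row(m) - col(m)) > 1)
  on <- sample(idx, min(n_contacts, length(idx)))
  m[on] <- 1
  m <- m + t(m)
  contact_map(m)
}

# Brute-force all-pairs shortest paths with minimum-hop tie-break by
# enumerating every simple path (exponential; fixtures must stay tiny).
bruteforce_paths <- function(dist, mask) {
  n <- nrow(dist)
  edge <- mask & row(mask) != col(mask)
  best_d <- matrix(Inf, n, n)
  best_h <- matrix(Inf, n, n)
  diag(best_d) <- 0
  diag(best_h) <- 0
  recurse <- function(path, len) {
    u <- path[length(path)]
    s <- path[1]
    if (length(path) > 1) {
      h <- length(path) - 1
      if (len < best_d[s, u] - 1e-12 ||
          (abs(len - best_d[s, u]) <= 1e-12 && h < best_h[s, u])) {
        best_d[s, u] <<- len
        best_h[s, u] <<- h
      }
    }
    for (v in which(edge[u, ])) {
      if (!(v %in% path)) recurse(c(path, v), len + dist[u, v])
    }
  }
  for (s in seq_len(n)) recurse(s, 0)
  ## undirected: enumeration covers both directions, so both are symmetric
  list(dist = best_d, hops = best_h)
}
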