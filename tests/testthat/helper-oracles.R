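# Independent brute-force oracles used across the test files. These are
# deliberately naive (loops, direct definitions) and share no code with the
# implementation they check.

# pointwise linear interpolation between bracketing detections, clamped at
# the observed endpoints
oracle_interp <- function(ts, vs, tout) {
  sapply(tout, function(t) {
    if (t <= ts[1]) return(vs[1])
    if (t >= ts[length(ts)]) return(vs[length(vs)])
    i <- max(which(ts <= t))
    if (ts[i] == t) return(vs[i])
    vs[i] + (vs[i + 1] - vs[i]) * (t - ts[i]) / (ts[i + 1] - ts[i])
  })
}

# Pearson r from the definition, one pair at a time
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# average local clustering from explicit triangle counting on an adjacency
# matrix; degree < 2 nodes contribute 0
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in 1:n) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_along(nb)) for (b in seq_len(a - 1))
      tri <- tri + adj[nb[a], nb[b]]
    cc[i] <- 2 * tri / (k * (k - 1))
  }
  mean(cc)
}

# all-pairs shortest paths by repeated BFS on an adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in 1:n) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (dist[w] > dist[v] + 1) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist
  }
  d
}

# exhaustive Boltzmann distribution over all 2^N states of a tiny torus
oracle_boltzmann <- function(L, T) {
  N <- L * L
  n_states <- 2^N
  codes <- 0:(n_states - 1)
  probs <- numeric(n_states)
  for (code in codes) {
    bits <- as.integer(intToBits(code))[1:N]
    spins <- ifelse(bits == 1L, 1L, -1L)
    E <- oracle_lattice_energy(spins, L)
    probs[code + 1] <- exp(-E / T)
  }
  probs / sum(probs)
}

# bond-once toroidal energy by explicit bond enumeration (row-major spins)
oracle_lattice_energy <- function(spins, L) {
  s <- matrix(spins, L, L, byrow = TRUE)
  E <- 0
  for (r in 1:L) for (c in 1:L) {
    E <- E - s[r, c] * s[r, c %% L + 1]   # right bond
    E <- E - s[r, c] * s[r %% L + 1, c]   # down bond
  }
  E
}

adj_from_graph <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

expect_tibble_cols <- function(x, cols) {
  testthat::expect_s3_class(x, "tbl_df")
  testthat::expect_true(all(cols %in% names(x)))
}
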