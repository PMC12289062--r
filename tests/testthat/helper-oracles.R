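# Independent brute-force reference implementations used across tests.

# local clustering by explicit triangle counting over neighbor pairs
brute_local_clustering <- function(g) {
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  vapply(seq_along(adj), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2L) return(0)
    tri <- 0L
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        if (nb[[b]] %in% adj[[nb[[a]]]]) tri <- tri + 1L
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# O(n^2) double-loop Kendall pair counter, both variants
brute_kendall <- function(x, y, variant = "tau_b") {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sx <- sign(x[j] - x[i])
      sy <- sign(y[j] - y[i])
      if (sx == 0) tx <- tx + 1L
      if (sy == 0) ty <- ty + 1L
      if (sx * sy > 0) nc <- nc + 1L
      if (sx * sy < 0) nd <- nd + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  if (variant == "tau_a") (nc - nd) / n0
  else (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

# random ER/BA graph batch shared by the oracle-equivalence checks
random_graph_batch <- function(n_graphs, n_min = 20, n_max = 120, seed = 99) {
  set.seed(seed)
  lapply(seq_len(n_graphs), function(i) {
    n <- sample(n_min:n_max, 1)
    if (i %% 2 == 0) {
      synth_graph("er", n, p = runif(1, 0.02, 0.15), seed = seed + i)
    } else {
      synth_graph("ba", n, m = sample(1:4, 1), seed = seed + i)
    }
  })
}
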