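#' Node degrees as a named map
#'
#' @param g An undirected igraph graph.
#' @return Named integer vector, one entry per node; names are node labels.
#' @export
degree_map <- function(g) {
  stopifnot_graph(g)
  d <- igraph::degree(g)
  stats::setNames(as.integer(d), node_names(g))
}

#' Whole-network summary statistics
#'
#' Computes the statistics conventionally reported for spreading-experiment
#' benchmark networks: node and edge counts, average degree
#' \eqn{\langle k\rangle = 2E/N}, average shortest-path distance `d` over the
#' largest connected component, average local clustering coefficient `c`
#' (nodes of degree < 2 contribute 0), the maximum k-shell index, and the
#' mean-field epidemic threshold
#' \eqn{\beta_{th} = \langle k\rangle / \langle k^2\rangle}.
#'
#' @param g An undirected igraph graph with at least 2 nodes.
#' @return An object of class `network_stats`: a list with elements
#'   `n`, `e`, `k`, `d`, `c`, `ks_max`, `beta_th`.
#' @examples
#' s <- network_summary(karate_graph())
#' round(s$k, 2)       # 4.59
#' round(s$beta_th, 3) # 0.129
#' @export
network_summary <- function(g) {
  stopifnot_graph(g)
  n <- igraph::vcount(g)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  e <- igraph::ecount(g)
  k <- 2 * e / n
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    message("graph is disconnected; average distance computed on the ",
            "largest connected component (", max(comp$csize), " nodes)")
    giant <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
  } else {
    giant <- g
  }
  d <- igraph::mean_distance(giant, directed = FALSE)
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  ks_max <- if (e > 0L) max(kshell_decompose(g)$ks) else 0L
  bt <- if (e > 0L) epidemic_threshold(g) else NA_real_
  structure(
    list(n = n, e = e, k = k, d = d, c = cc,
         ks_max = as.integer(ks_max), beta_th = bt),
    class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    "network: N=%d E=%d  k=%.2f  d=%.2f  c=%.2f  Ksmax=%d  beta_th=%.3f\n",
    x$n, x$e, x$k, x$d, x$c, x$ks_max, x$beta_th))
  invisible(x)
}

#' @export
as.data.frame.network_stats <- function(x, ...) {
  data.frame(n = x$n, e = x$e, k = x$k, d = x$d, c = x$c,
             ks_max = x$ks_max, beta_th = x$beta_th)
}
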