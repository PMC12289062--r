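#' Mean-field epidemic threshold
#'
#' \deqn{\beta_{th} \approx \langle k\rangle / \langle k^2\rangle}
#' with \eqn{\langle k\rangle} the mean degree and \eqn{\langle k^2\rangle}
#' the mean squared degree. Infection probabilities above this value allow
#' network-wide outbreaks on uncorrelated networks; spreading-power
#' experiments conventionally run at beta slightly above it.
#'
#' @param g An undirected igraph graph with at least one edge.
#' @return A single number in (0, 1].
#' @examples
#' epidemic_threshold(igraph::make_ring(10)) # 2-regular: 1/2
#' @export
epidemic_threshold <- function(g) {
  stopifnot_graph(g)
  if (igraph::ecount(g) == 0L) stop("edgeless graph has no threshold", call. = FALSE)
  d <- igraph::degree(g)
  mean(d) / mean(d^2)
}

#' SIR simulation configuration
#'
#' @param beta Per-contact infection probability in \[0, 1\]. `NULL` defaults
#'   to `1.1 * epidemic_threshold(g)` at run time ("slightly above
#'   threshold").
#' @param gamma Per-step recovery probability in (0, 1]. Default 1: each
#'   node is infectious for exactly one step, the convention of the
#'   original k-shell spreading studies.
#' @param reps Number of independent repetitions (default 100).
#' @param max_steps Step cap per run (default 10000, effectively unbounded
#'   for the network sizes considered here).
#' @param seed Master RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `sir_config`.
#' @export
sir_config <- function(beta = NULL, gamma = 1, reps = 100L,
                       max_steps = 10000L, seed = NULL) {
  if (!is.null(beta) && (beta < 0 || beta > 1)) {
    stop("beta must lie in [0, 1]", call. = FALSE)
  }
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]", call. = FALSE)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  structure(list(beta = beta, gamma = gamma, reps = as.integer(reps),
                 max_steps = as.integer(max_steps), seed = seed),
            class = "sir_config")
}

resolve_beta <- function(g, cfg) {
  if (!is.null(cfg$beta)) cfg$beta else 1.1 * epidemic_threshold(g)
}

# deterministic per-node sub-seed below 2^31, mixing master seed and index
derive_seed <- function(master, i) {
  (as.double(master) * 1000003 + as.double(i) * 10007 + 1) %% 2147483629
}

# core synchronous step loop over integer status (0=S, 1=I, 2=R);
# draws from the current RNG state
sir_engine <- function(adj, n, sources_idx, beta, gamma, max_steps) {
  status <- integer(n)
  status[sources_idx] <- 1L
  s_hist <- n - length(sources_idx)
  i_hist <- length(sources_idx)
  r_hist <- 0L
  steps <- 0L
  while (any(status == 1L) && steps < max_steps) {
    infected <- which(status == 1L)
    # (1) every infected node exposes each susceptible neighbor independently
    newly <- integer(0)
    if (beta > 0) {
      targets <- unlist(adj[infected], use.names = FALSE)
      targets <- targets[status[targets] == 0L]
      if (length(targets)) {
        hit <- targets[stats::runif(length(targets)) < beta]
        newly <- unique(hit)
      }
    }
    # (2) recovery applies only to nodes infected BEFORE this step
    rec <- infected[stats::runif(length(infected)) < gamma]
    status[rec] <- 2L
    status[newly] <- 1L
    steps <- steps + 1L
    s_hist <- c(s_hist, sum(status == 0L))
    i_hist <- c(i_hist, sum(status == 1L))
    r_hist <- c(r_hist, sum(status == 2L))
  }
  list(per_step = data.frame(step = 0:steps, S = s_hist, I = i_hist, R = r_hist),
       final_recovered = sum(status != 0L),
       steps_to_absorption = steps)
}

#' Run one discrete-time SIR simulation
#'
#' Synchronous update with infect-then-recover ordering: per step, (1) every
#' currently infected node independently infects each susceptible neighbor
#' with probability `beta` (a susceptible node with several infected
#' neighbors gets one independent chance per neighbor); (2) every node that
#' was already infected before the step recovers with probability `gamma` —
#' newly infected nodes cannot recover in the step they were infected. The
#' run stops when no infected nodes remain. In the `beta = 1, gamma = 1`
#' limit this is exactly a breadth-first wave.
#'
#' `final_recovered` counts recovered plus still-infected nodes at stop
#' (identical when the run reaches absorption).
#'
#' @param g An undirected simple igraph graph.
#' @param sources Character/integer vector of initially infected nodes.
#' @param cfg A [sir_config()]. Its `seed` (when non-`NULL`) seeds the run.
#' @return An object of class `sir_run`: list with `per_step` (data.frame of
#'   S/I/R counts, step 0 = initial state), `final_recovered`,
#'   `steps_to_absorption`.
#' @export
sir_run <- function(g, sources, cfg = sir_config()) {
  stopifnot_graph(g)
  if (length(sources) == 0L) stop("source set must be non-empty", call. = FALSE)
  labels <- node_names(g)
  idx <- if (is.numeric(sources)) as.integer(sources) else match(as.character(sources), labels)
  if (anyNA(idx) || any(idx < 1L | idx > length(labels))) {
    stop("unknown source node(s)", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- sir_engine(adjacency_index(g), igraph::vcount(g), unique(idx),
                    resolve_beta(g, cfg), cfg$gamma, cfg$max_steps)
  class(res) <- "sir_run"
  res
}

#' Per-node spreading power under SIR
#'
#' For every node, runs `cfg$reps` independent single-source SIR simulations
#' seeded at that node and averages the final recovered count — the SIR
#' ground truth against which centrality rankings are scored. Each node gets
#' its own RNG stream derived from `cfg$seed`, so the table is reproducible
#' and independent of node iteration order.
#'
#' @param g An undirected simple igraph graph.
#' @param cfg A [sir_config()].
#' @return An object of class `spreading_power`: list with `mean_final_R`
#'   (named numeric vector) and `config`.
#' @export
spreading_power <- function(g, cfg = sir_config()) {
  stopifnot_graph(g)
  n <- igraph::vcount(g)
  adj <- adjacency_index(g)
  beta <- resolve_beta(g, cfg)
  master <- if (is.null(cfg$seed)) {
    sample.int(2147483600L, 1L) # anchor unseeded calls to one reported master
  } else cfg$seed
  out <- numeric(n)
  for (v in seq_len(n)) {
    set.seed(derive_seed(master, v))
    tot <- 0
    for (r in seq_len(cfg$reps)) {
      tot <- tot + sir_engine(adj, n, v, beta, cfg$gamma, cfg$max_steps)$final_recovered
    }
    out[v] <- tot / cfg$reps
  }
  structure(list(mean_final_R = stats::setNames(out, node_names(g)),
                 config = cfg, beta_used = beta, master_seed = master),
            class = "spreading_power")
}

#' @export
print.spreading_power <- function(x, ...) {
  cat("spreading power: ", length(x$mean_final_R), " nodes, beta=",
      signif(x$beta_used, 4), ", gamma=", x$config$gamma,
      ", reps=", x$config$reps, "\n", sep = "")
  invisible(x)
}

#' Mean cumulative-recovered curve for a seed set
#'
#' Infects all `seeds` at time 0 and averages the per-step recovered count
#' over `cfg$reps` runs — the propagation curve
#' used to compare the top-k node sets chosen by different ranking methods.
#' Runs shorter than the longest one are carried forward at their final
#' value, so the mean curve is defined on a common time axis and is
#' non-decreasing.
#'
#' @param g An undirected simple igraph graph.
#' @param seeds Nodes infected at time 0 (e.g. a method's top 10).
#' @param cfg A [sir_config()]; the top-k experiments conventionally use
#'   `gamma = 0.5`.
#' @return data.frame with columns `step` and `mean_R`.
#' @export
topk_spread_curve <- function(g, seeds, cfg = sir_config(gamma = 0.5)) {
  stopifnot_graph(g)
  if (length(seeds) < 1L) stop("need at least one seed", call. = FALSE)
  labels <- node_names(g)
  idx <- if (is.numeric(seeds)) as.integer(seeds) else match(as.character(seeds), labels)
  if (anyNA(idx)) stop("unknown seed node(s)", call. = FALSE)
  adj <- adjacency_index(g)
  n <- igraph::vcount(g)
  beta <- resolve_beta(g, cfg)
  master <- if (is.null(cfg$seed)) sample.int(2147483600L, 1L) else cfg$seed
  curves <- vector("list", cfg$reps)
  for (r in seq_len(cfg$reps)) {
    set.seed(derive_seed(master, r))
    run <- sir_engine(adj, n, unique(idx), beta, cfg$gamma, cfg$max_steps)
    curves[[r]] <- run$per_step$R
  }
  len <- max(vapply(curves, length, integer(1)))
  acc <- vapply(curves, function(cv) c(cv, rep(cv[length(cv)], len - length(cv))),
                numeric(len))
  data.frame(step = seq_len(len) - 1L, mean_R = rowMeans(acc))
}
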