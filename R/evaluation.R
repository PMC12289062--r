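#' Ranking monotonicity index
#'
#' Quantifies how finely a ranking separates nodes:
#' \deqn{M(R) = \left(1 - \frac{\sum_r n_r (n_r - 1)}{N (N - 1)}\right)^2}
#' where \eqn{n_r} is the number of nodes sharing dense rank level r.
#' M = 1 when every node has its own rank; M = 0 when all nodes tie.
#' M is invariant under any strictly monotone transform of the scores, so
#' it compares methods regardless of score normalization.
#'
#' @param r A `node_ranking` (see [to_ranking()]), a [score_map()], or a
#'   named numeric score vector (the latter two are ranked first).
#' @return A single number in \[0, 1\].
#' @examples
#' monotonicity(score_map("toy", c(a = 3, b = 2, c = 1))) # 1
#' @export
monotonicity <- function(r) {
  if (!inherits(r, "node_ranking")) r <- to_ranking(r)
  sizes <- lengths(r$groups)
  n <- sum(sizes)
  if (n < 2L) stop("monotonicity needs at least 2 ranked nodes", call. = FALSE)
  (1 - sum(sizes * (sizes - 1)) / (n * (n - 1)))^2
}

#' Kendall rank correlation between two score sequences
#'
#' `tau_a = 2 (Nc - Nd) / (n (n - 1))` with Nc/Nd the concordant and
#' discordant pair counts (ties count in neither); `tau_b` divides
#' `Nc - Nd` by the geometric mean of the tie-corrected pair counts.
#' With ties present tau-a cannot reach 1; tau-b is the headline variant
#' here because both SIR spreading power and several centralities tie
#' heavily.
#'
#' @param x,y Numeric vectors of equal length, aligned by node.
#' @param variant `"tau_b"` (default) or `"tau_a"`.
#' @return A single number in \[-1, 1\].
#' @examples
#' kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4), variant = "tau_a") # 2/3
#' @export
kendall_tau <- function(x, y, variant = c("tau_b", "tau_a")) {
  variant <- match.arg(variant)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  # vectorized pair signs; O(n^2) memory, fine for the network sizes here
  dx <- sign(outer(x, x, "-")[upper.tri(diag(n))])
  dy <- sign(outer(y, y, "-")[upper.tri(diag(n))])
  prod_ <- dx * dy
  nc <- sum(prod_ > 0)
  nd <- sum(prod_ < 0)
  n0 <- n * (n - 1) / 2
  if (variant == "tau_a") return((nc - nd) / n0)
  tx <- sum(dx == 0)
  ty <- sum(dy == 0)
  if (tx == n0 || ty == n0) {
    stop("tau-b undefined for a constant sequence", call. = FALSE)
  }
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

#' Complementary cumulative distribution of rank levels
#'
#' For each dense rank level r, the fraction of nodes ranked at level r or
#' deeper (numerically `>= r`). A slowly decaying curve (close to the
#' diagonal when plotted against level/N) indicates a finely discriminating
#' ranking; rapid decay means many nodes share the top levels.
#'
#' @param s A [score_map()], named score vector, or `node_ranking`.
#' @return data.frame with columns `rank_level` and `ccdf` (from 1 down to
#'   `n_last / N`).
#' @export
ccdf <- function(s) {
  r <- if (inherits(s, "node_ranking")) s else to_ranking(s)
  sizes <- lengths(r$groups)
  n <- sum(sizes)
  frac <- rev(cumsum(rev(sizes))) / n
  data.frame(rank_level = seq_along(sizes), ccdf = frac)
}

#' Rank-frequency distribution
#'
#' Number of nodes at each dense rank level — the data behind
#' rank-occupancy histograms used to compare how finely methods split the
#' node set.
#'
#' @param s A [score_map()], named score vector, or `node_ranking`.
#' @return data.frame with columns `rank_level` and `count`; counts sum
#'   to N.
#' @export
rank_frequency <- function(s) {
  r <- if (inherits(s, "node_ranking")) s else to_ranking(s)
  data.frame(rank_level = seq_along(r$groups), count = lengths(r$groups))
}

#' Compare ranking methods against SIR spreading power
#'
#' Computes each method's score map, its monotonicity M, and its Kendall
#' correlation (both variants) against the per-node SIR spreading power —
#' the standard benchmark table for influential-spreader methods.
#'
#' @param g An undirected simple igraph graph.
#' @param methods Character vector of built-in names (`"KTD"`, `"dc"`,
#'   `"bc"`, `"cc"`, `"ks"`, `"ks_plus"`) and/or a named list mixing names
#'   and plug-in functions `g -> score_map`.
#' @param cfg A [sir_config()]; `beta` must be positive (a zero-beta ground
#'   truth is constant and carries no ranking information).
#' @return An object of class `eval_report`: data.frame with columns
#'   `method`, `monotonicity`, `tau_a`, `tau_b`, plus attributes
#'   `beta_used`, `gamma`, `reps`.
#' @export
compare_methods <- function(g, methods = c("KTD", "dc", "bc", "cc", "ks", "ks_plus"),
                            cfg = sir_config()) {
  stopifnot_graph(g)
  beta <- resolve_beta(g, cfg)
  if (beta <= 0) stop("SIR comparison needs beta > 0", call. = FALSE)
  if (!is.list(methods)) methods <- as.list(methods)
  nm <- names(methods)
  if (is.null(nm)) nm <- rep("", length(methods))
  labels <- ifelse(nm != "", nm,
                   vapply(methods, function(m) if (is.character(m)) m else "custom",
                          character(1)))
  sp <- spreading_power(g, cfg)
  truth <- sp$mean_final_R
  rows <- lapply(seq_along(methods), function(i) {
    sm <- resolve_method(g, methods[[i]], name = labels[[i]])
    sc <- sm$scores[names(truth)]
    tb <- tryCatch(kendall_tau(sc, truth, variant = "tau_b"),
                   error = function(e) {
                     message("tau-b undefined for method '", labels[[i]],
                             "' (constant sequence); reporting NA")
                     NA_real_
                   })
    data.frame(method = labels[[i]],
               monotonicity = monotonicity(sm),
               tau_a = kendall_tau(sc, truth, variant = "tau_a"),
               tau_b = tb)
  })
  out <- do.call(rbind, rows)
  attr(out, "beta_used") <- sp$beta_used
  attr(out, "gamma") <- cfg$gamma
  attr(out, "reps") <- cfg$reps
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("method comparison vs SIR (beta=%.4g, gamma=%g, reps=%d)\n",
              attr(x, "beta_used"), attr(x, "gamma"), attr(x, "reps")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
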