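#' K-shell decomposition with a global iteration factor
#'
#' Peels the graph shell by shell (k = 1, 2, 3, ...). Within shell k the
#' peeling is simultaneous: every pass removes all currently remaining
#' nodes whose residual degree is at most k, assigns them k-shell value
#' `KS = k`, and stamps them with the current global round counter `IT`.
#' The counter starts at 1, increments after every non-empty pass, and never
#' resets when the shell index advances — so peripheral nodes peeled early
#' carry a small iteration factor and core nodes a large one, and the
#' layering is strict: `KS[i] < KS[j]` implies `IT[i] < IT[j]`.
#'
#' `KS` equals the classical coreness; `IT` is the extra information this
#' decomposition records. Isolated nodes (degree 0 in the input) are removed
#' in a first pass with `KS = 0`, `IT = 1`.
#'
#' @param g An undirected simple igraph graph with at least one node.
#' @return An object of class `kshell_decomposition`: a list with
#'   \describe{
#'     \item{ks}{named integer vector of k-shell values}
#'     \item{it}{named integer vector of iteration factors (rounds, from 1)}
#'     \item{it_max}{total number of removal rounds}
#'     \item{rounds}{data.frame with columns `round`, `shell_k`, `node`
#'       logging which nodes each pass removed}
#'   }
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, c - d) # path on 4 nodes
#' d <- kshell_decompose(g)
#' d$ks      # all 1
#' d$it      # endpoints 1, middle pair 2
#' d$it_max  # 2
#' @export
kshell_decompose <- function(g) {
  stopifnot_graph(g)
  n <- igraph::vcount(g)
  labels <- node_names(g)
  adj <- adjacency_index(g)
  degc <- as.integer(igraph::degree(g))

  ks <- it <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  round_i <- 0L
  log_round <- integer(0); log_k <- integer(0); log_node <- integer(0)

  remove_pass <- function(rem, k) {
    # simultaneous removal: degrees of survivors drop only after the
    # whole pass is collected, so the result is iteration-order free
    round_i <<- round_i + 1L
    ks[rem] <<- k
    it[rem] <<- round_i
    alive[rem] <<- FALSE
    for (v in rem) {
      nb <- adj[[v]]
      nb <- nb[alive[nb]]
      degc[nb] <<- degc[nb] - 1L
    }
    log_round <<- c(log_round, rep(round_i, length(rem)))
    log_k <<- c(log_k, rep(k, length(rem)))
    log_node <<- c(log_node, rem)
  }

  iso <- which(degc == 0L)
  if (length(iso)) remove_pass(iso, 0L)

  k <- 1L
  while (any(alive)) {
    repeat {
      rem <- which(alive & degc <= k)
      if (!length(rem)) break
      remove_pass(rem, k)
    }
    k <- k + 1L
  }

  structure(
    list(ks = stats::setNames(ks, labels),
         it = stats::setNames(it, labels),
         it_max = round_i,
         rounds = data.frame(round = log_round, shell_k = log_k,
                             node = labels[log_node])),
    class = "kshell_decomposition")
}

#' @export
print.kshell_decomposition <- function(x, ...) {
  cat("k-shell decomposition:", length(x$ks), "nodes,",
      max(x$ks), "max shell,", x$it_max, "removal rounds\n")
  invisible(x)
}

#' @export
as.data.frame.kshell_decomposition <- function(x, ...) {
  data.frame(node = names(x$ks), ks = unname(x$ks), it = unname(x$it))
}

#' Brute-force coreness (test oracle)
#'
#' Independent reference for the `ks` values of [kshell_decompose()]: for
#' k = 1, 2, ... it deletes nodes of degree < k one at a time until none
#' remain, and records the largest k at which each node survives. Quadratic
#' and deliberately naive; intended for graphs up to a few thousand nodes.
#'
#' @param g An undirected simple igraph graph.
#' @return Named integer vector of coreness values.
#' @export
coreness_oracle <- function(g) {
  stopifnot_graph(g)
  n <- igraph::vcount(g)
  adj <- adjacency_index(g)
  deg0 <- as.integer(igraph::degree(g))
  core <- rep(0L, n)
  k <- 1L
  alive <- rep(TRUE, n)
  repeat {
    degc <- deg0
    alive[] <- TRUE
    # strip to the k-core: delete any one node of degree < k, repeat
    repeat {
      v <- which(alive & degc < k)
      if (!length(v)) break
      v <- v[[1L]]
      alive[v] <- FALSE
      nb <- adj[[v]]
      degc[nb] <- degc[nb] - 1L
    }
    if (!any(alive)) break
    core[alive] <- k
    k <- k + 1L
  }
  stats::setNames(core, node_names(g))
}
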