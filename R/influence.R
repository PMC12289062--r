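#' Construct a score map
#'
#' A score map pairs a method name with one finite real score per node.
#' All ranking and evaluation functions consume this container.
#'
#' @param method Method name (e.g. `"KTD"`, `"dc"`).
#' @param scores Named numeric vector of node scores.
#' @return An object of class `score_map`.
#' @export
score_map <- function(method, scores) {
  if (is.null(names(scores)) || anyNA(names(scores))) {
    stop("scores must be a named vector", call. = FALSE)
  }
  if (!all(is.finite(scores))) {
    stop("all scores must be finite", call. = FALSE)
  }
  structure(list(method = method, scores = scores), class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat("score_map [", x$method, "]: ", length(x$scores), " nodes\n", sep = "")
  print(utils::head(sort(x$scores, decreasing = TRUE), 5L))
  invisible(x)
}

#' Direct (within-shell refined) node influence
#'
#' Refines the k-shell value of each node with its normalized iteration
#' factor and normalized degree:
#' \deqn{C_i = KS_i + \frac{IT_i}{IT_{max}} \cdot \frac{deg_i}{deg_{max}}}
#' Both normalizers are taken over the whole network, and `degrees` are the
#' ORIGINAL full-graph degrees, not residual degrees at removal time. The
#' refinement term lies in (0, 1], so shell order is preserved:
#' `KS[i] < C[i] <= KS[i] + 1`, and a higher shell always outranks a lower
#' one.
#'
#' @param decomposition A [kshell_decompose()] result (or any list with
#'   named `ks`, `it` vectors and `it_max`).
#' @param degrees Named integer vector of original degrees, same node set.
#' @return A [score_map()] with method `"C"`.
#' @examples
#' t1 <- table1_fixture()
#' d <- list(ks = setNames(t1$ks, t1$node), it = setNames(t1$it, t1$node),
#'           it_max = max(t1$it))
#' ci <- direct_influence(d, setNames(t1$deg, t1$node))
#' ci$scores[["10"]] # 4
#' @export
direct_influence <- function(decomposition, degrees) {
  ks <- decomposition$ks
  it <- decomposition$it
  it_max <- decomposition$it_max
  if (is.null(names(degrees))) stop("degrees must be named", call. = FALSE)
  if (!setequal(names(ks), names(degrees))) {
    stop("node sets of decomposition and degrees differ", call. = FALSE)
  }
  degrees <- degrees[names(ks)]
  deg_max <- max(degrees)
  if (it_max < 1L || deg_max < 1L) {
    stop("need it_max >= 1 and a positive maximum degree", call. = FALSE)
  }
  ci <- ks + (it / it_max) * (degrees / deg_max)
  score_map("C", ci)
}

#' KTD final influence score
#'
#' The full pipeline: k-shell decomposition with iteration factors, direct
#' influence per node, then aggregation over the ORIGINAL graph's neighbor
#' sets:
#' \deqn{E_i = C_i + \sum_{j \in N_i} C_j}
#' so two nodes with identical shell, iteration factor and degree are still
#' separated when their neighborhoods differ in influence.
#'
#' @param g An undirected simple igraph graph.
#' @return A [score_map()] with method `"KTD"`.
#' @examples
#' sm <- ktd_score(karate_graph())
#' head(sort(sm$scores, decreasing = TRUE), 3)
#' @export
ktd_score <- function(g) {
  stopifnot_graph(g)
  dec <- kshell_decompose(g)
  ci <- direct_influence(dec, degree_map(g))$scores
  adj <- adjacency_index(g)
  ei <- ci + vapply(adj, function(nb) sum(ci[nb]), numeric(1))
  score_map("KTD", stats::setNames(ei, names(ci)))
}

#' Baseline centrality scores
#'
#' The comparison methods conventionally used against k-shell refinements:
#' \describe{
#'   \item{dc}{degree centrality (raw degree)}
#'   \item{bc}{shortest-path betweenness (unnormalized; all evaluation
#'     metrics here are rank-based, so normalization is immaterial)}
#'   \item{cc}{closeness centrality (per-component convention for
#'     disconnected graphs)}
#'   \item{ks}{k-shell (coreness) value}
#'   \item{ks_plus}{extended k-shell, `KS + deg/deg_max` — coreness refined
#'     by degree relative to the maximum degree}
#' }
#'
#' @param g An undirected simple igraph graph.
#' @param method One of `"dc"`, `"bc"`, `"cc"`, `"ks"`, `"ks_plus"`.
#' @return A [score_map()].
#' @export
baseline_scores <- function(g, method = c("dc", "bc", "cc", "ks", "ks_plus")) {
  stopifnot_graph(g)
  method <- match.arg(method)
  labels <- node_names(g)
  s <- switch(method,
    dc = as.numeric(igraph::degree(g)),
    bc = igraph::betweenness(g, directed = FALSE),
    cc = suppressWarnings(igraph::closeness(g, mode = "all")),
    ks = as.numeric(kshell_decompose(g)$ks),
    ks_plus = {
      d <- igraph::degree(g)
      as.numeric(kshell_decompose(g)$ks) + d / max(d)
    })
  s[!is.finite(s)] <- 0 # closeness of isolated nodes
  score_map(method, stats::setNames(as.numeric(s), labels))
}

#' Resolve a ranking method to a score map
#'
#' Accepts a built-in method name (`"KTD"` or any [baseline_scores()] name)
#' or a plug-in: a function `g -> score_map` (or `g ->` named numeric
#' vector) supplied under a user-chosen name. This is the extension point
#' for third-party k-shell refinements whose formulas live elsewhere.
#'
#' @param g An undirected simple igraph graph.
#' @param method Method name, or a function.
#' @param name Label used when `method` is a function.
#' @return A [score_map()].
#' @export
resolve_method <- function(g, method, name = "custom") {
  if (is.function(method)) {
    out <- method(g)
    if (inherits(out, "score_map")) return(out)
    return(score_map(name, out))
  }
  if (identical(method, "KTD")) return(ktd_score(g))
  baseline_scores(g, method)
}

#' Dense ranking of a score map
#'
#' Scores are rounded to `tol_digits` decimals (floating-point centralities
#' such as betweenness make exact-equality grouping brittle), grouped by
#' equality, ordered by decreasing score, and assigned dense rank ids
#' 1, 2, 3, ... Tied nodes share a rank level.
#'
#' @param s A [score_map()] or named numeric vector.
#' @param tol_digits Decimals kept before tie grouping (default 10).
#' @return An object of class `node_ranking`: list with `groups` (list of
#'   character vectors, descending score), `rank_of` (named integer vector),
#'   `group_scores`, `n_levels`, and `method`.
#' @examples
#' r <- to_ranking(score_map("toy", c(a = 2, b = 2, c = 1)))
#' r$rank_of # a=1 b=1 c=2
#' @export
to_ranking <- function(s, tol_digits = 10L) {
  if (inherits(s, "score_map")) {
    method <- s$method
    scores <- s$scores
  } else {
    method <- "scores"
    scores <- s
  }
  if (is.null(names(scores))) stop("scores must be named", call. = FALSE)
  rs <- round(scores, tol_digits)
  lv <- sort(unique(rs), decreasing = TRUE)
  rank_of <- match(rs, lv)
  groups <- split(names(scores), factor(rank_of, levels = seq_along(lv)))
  names(groups) <- NULL
  structure(
    list(groups = groups,
         rank_of = stats::setNames(as.integer(rank_of), names(scores)),
         group_scores = lv,
         n_levels = length(lv),
         method = method),
    class = "node_ranking")
}

#' @export
print.node_ranking <- function(x, ...) {
  cat("ranking [", x$method, "]: ", length(x$rank_of), " nodes in ",
      x$n_levels, " dense rank levels\n", sep = "")
  invisible(x)
}
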