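#' Zachary karate club network
#'
#' Loads the bundled 34-node, 78-edge karate club friendship network, the
#' classic small benchmark for spreader-ranking experiments (mean degree
#' 4.59, max k-shell 4). Node labels are "1".."34" following the common
#' published listing.
#'
#' @return An undirected simple igraph graph.
#' @examples
#' g <- karate_graph()
#' igraph::ecount(g) # 78
#' @export
karate_graph <- function() {
  path <- system.file("extdata", "karate.edgelist", package = "ktdrank",
                      mustWork = TRUE)
  load_edgelist(path)
}

#' Worked-example decomposition table
#'
#' An 18-node worked example of the iteration-factor decomposition: per node
#' the iteration factor `it` (removal round, global across shells, 1..6),
#' k-shell value `ks` (1..3) and original degree `deg`. Three nodes
#' illustrate the scoring rationale: nodes 4 and 5 share (it, ks) but differ
#' in degree; nodes 7 and 8 share all three values and are separated only by
#' neighbor aggregation. The example's edge list is not recoverable from the
#' table, so this fixture is input data for the scoring layer, never
#' recomputed from a graph.
#'
#' @return data.frame with columns `node` (character), `it`, `ks`, `deg`
#'   (integers), 18 rows; `it_max` attribute is 6, max degree 6.
#' @export
table1_fixture <- function() {
  df <- data.frame(
    node = as.character(1:18),
    it  = c(1L, 1L, 1L, 2L, 2L, 3L, 4L, 4L, 1L, 6L, 6L, 6L, 6L, 5L, 4L, 1L, 2L, 1L),
    ks  = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 1L, 3L, 3L, 3L, 3L, 2L, 2L, 1L, 1L, 1L),
    deg = c(1L, 1L, 1L, 3L, 2L, 3L, 3L, 3L, 1L, 6L, 4L, 3L, 5L, 3L, 4L, 1L, 2L, 1L)
  )
  attr(df, "it_max") <- 6L
  df
}

#' Synthetic test graphs
#'
#' Reproducible generators for the graph families used throughout the test
#' suite: Erdos-Renyi `G(n, p)`, Barabasi-Albert preferential attachment,
#' and the deterministic path / cycle / star / clique families, plus uniform
#' random recursive trees. All outputs are simple undirected graphs with
#' character labels "1".."n".
#'
#' @param kind One of `"er"`, `"ba"`, `"path"`, `"cycle"`, `"star"`,
#'   `"clique"`, `"tree"`.
#' @param n Number of nodes (>= 2; `>= 1` allowed for clique).
#' @param p Edge probability for `"er"` (in \[0, 1\]).
#' @param m Edges per new node for `"ba"` (>= 1).
#' @param seed RNG seed for the random families; same seed, same graph.
#' @return An undirected simple igraph graph.
#' @examples
#' g <- synth_graph("er", n = 50, p = 0.1, seed = 1)
#' identical(igraph::as_edgelist(g),
#'           igraph::as_edgelist(synth_graph("er", 50, p = 0.1, seed = 1)))
#' @export
synth_graph <- function(kind = c("er", "ba", "path", "cycle", "star",
                                 "clique", "tree"),
                        n, p = NULL, m = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (n < 2L && kind != "clique") stop("n must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- switch(kind,
    er = {
      if (is.null(p) || p < 0 || p > 1) stop("er needs p in [0, 1]", call. = FALSE)
      igraph::sample_gnp(n, p, directed = FALSE)
    },
    ba = {
      if (is.null(m) || m < 1L) stop("ba needs m >= 1", call. = FALSE)
      igraph::sample_pa(n, m = m, directed = FALSE)
    },
    path = igraph::make_lattice(n, dim = 1),
    cycle = igraph::make_ring(n),
    star = igraph::make_star(n, mode = "undirected", center = 1),
    clique = igraph::make_full_graph(n),
    tree = {
      # uniform random recursive tree: node i attaches to a random earlier node
      parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
      igraph::make_graph(rbind(parent, 2:n), directed = FALSE)
    })
  g <- igraph::simplify(g)
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(igraph::vcount(g))))
}

#' Fetch a benchmark network by name (may require network access)
#'
#' Loads one of the larger public benchmark networks that are not bundled.
#' Looks for a plain edge list at `dest`; if absent and `url` is given, the
#' file is downloaded there first. The loaded graph is validated against
#' recorded node/edge counts, so a wrong or corrupted file fails loudly
#' rather than silently shifting results. The canonical distributions of
#' these networks (e.g. Lusseau's bottlenose-dolphin social network) are
#' hosted in several formats; convert to a two-column edge list before use.
#'
#' @param name Currently `"dolphins"` (62 nodes, 159 edges).
#' @param dest Local cache path; default under `tempdir()`.
#' @param url Optional URL of a plain edge list, downloaded to `dest` when
#'   no cached copy exists.
#' @return An undirected simple igraph graph.
#' @export
fetch_network <- function(name = "dolphins",
                          dest = file.path(tempdir(), paste0(name, ".edgelist")),
                          url = NULL) {
  catalog <- list(dolphins = list(n = 62L, e = 159L))
  if (!name %in% names(catalog)) stop("unknown network: ", name, call. = FALSE)
  entry <- catalog[[name]]
  if (!file.exists(dest)) {
    if (is.null(url)) {
      stop("no cached copy of '", name, "' at ", dest,
           " and no url given; download the edge list first", call. = FALSE)
    }
    utils::download.file(url, dest, quiet = TRUE)
  }
  g <- load_edgelist(dest)
  if (igraph::vcount(g) != entry$n || igraph::ecount(g) != entry$e) {
    stop(name, " fixture at ", dest, " has N=", igraph::vcount(g), " E=",
         igraph::ecount(g), "; expected N=", entry$n, " E=", entry$e,
         call. = FALSE)
  }
  g
}
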