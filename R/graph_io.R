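#' Read an undirected simple graph from an edge-list file
#'
#' Parses a plain-text edge list (one edge per line, whitespace- or
#' comma-delimited, `#` starts a comment) into an undirected [igraph] graph.
#' Node labels are kept verbatim as character vertex names. Self-loops and
#' duplicate edges are dropped with a warning, so the result is always a
#' simple graph.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field separator. `NULL` (default) splits on any run of
#'   whitespace and additionally treats commas as separators, so both
#'   `"a b"` and `"a,b"` parse.
#' @return An undirected simple `igraph` graph with character vertex names.
#' @examples
#' f <- tempfile()
#' writeLines(c("1 2", "2 3", "3 1"), f)
#' g <- load_edgelist(f)
#' igraph::vcount(g) # 3
#' @export
load_edgelist <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  if (!length(keep)) stop("no edges in ", path, ": empty graph", call. = FALSE)
  split_re <- if (is.null(delimiter)) "[,[:space:]]+" else delimiter
  ends <- matrix(NA_character_, nrow = length(keep), ncol = 2L)
  for (i in seq_along(keep)) {
    tok <- strsplit(trimws(lines[[keep[i]]]), split_re)[[1]]
    tok <- tok[tok != ""]
    if (length(tok) < 2L) {
      stop("malformed edge list line ", keep[i], " in ", path,
           ": need at least 2 tokens, got ", length(tok), call. = FALSE)
    }
    ends[i, ] <- tok[1:2]
  }
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  if (n_loops > 0L || n_multi > 0L) {
    warning("dropped ", n_loops, " self-loop(s) and ", n_multi,
            " duplicate edge(s) while simplifying ", path, call. = FALSE)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  if (igraph::vcount(g) == 0L) stop("empty graph in ", path, call. = FALSE)
  g
}

#' Write a graph as a plain-text edge list
#'
#' Inverse of [load_edgelist()]: one `u v` pair per line, vertex names as-is.
#'
#' @param g An undirected igraph graph.
#' @param path Output file path.
#' @param delimiter Separator between the two endpoints (default single space).
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path, delimiter = " ") {
  stopifnot_graph(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1], el[, 2], sep = delimiter), path)
  invisible(path)
}

#' Coerce input to a simple undirected graph
#'
#' Directed graphs are symmetrized and edge weights/attributes discarded,
#' each with a warning; parallel edges and loops are removed. Used by every
#' entry point so downstream code can assume the simple-undirected contract.
#'
#' @param g An igraph graph.
#' @return An undirected simple igraph graph.
#' @export
as_simple_undirected <- function(g) {
  stopifnot_graph(g)
  if (igraph::is_directed(g)) {
    warning("directed input symmetrized to an undirected graph", call. = FALSE)
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  if (igraph::is_weighted(g)) {
    warning("edge weights ignored", call. = FALSE)
    g <- igraph::delete_edge_attr(g, "weight")
  }
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    g <- igraph::simplify(g)
  }
  g
}
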