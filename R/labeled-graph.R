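#' Vertex-labeled graph
#'
#' The common graph container consumed by the random-walk kernel engine.
#' Vertices carry opaque label strings; edges are unlabeled (edge labels are
#' promoted to vertices beforehand, see [edge_to_vertex_transform()]).
#' Graphs may be directed -- the non-tottering transform produces directed
#' graphs -- and may carry non-uniform start weights for the walk's initial
#' distribution.
#'
#' @param labels character vector of vertex labels; length gives the vertex
#'   count (must be at least 1).
#' @param edges two-column integer matrix of vertex indices, one row per
#'   edge. May have zero rows. Self-loops and duplicate edges (in either
#'   orientation for undirected graphs) are rejected.
#' @param directed logical; if `TRUE` each row is an arc from column 1 to
#'   column 2.
#' @param start optional non-negative start-weight vector, one entry per
#'   vertex, with positive sum; `NULL` means uniform over all vertices.
#' @param id optional identifier carried through to Gram matrix dimnames.
#' @return an object of class `labeled_graph`.
#' @examples
#' g <- labeled_graph(c("a", "b", "c"), rbind(c(1, 2), c(2, 3)))
#' n_vertices(g)
#' @export
labeled_graph <- function(labels, edges = matrix(integer(0), 0, 2),
                          directed = FALSE, start = NULL, id = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 1L) {
    stop("a labeled_graph needs at least one vertex")
  }
  edges <- as_edge_matrix(edges)
  n <- length(labels)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n)) {
      stop("edge endpoints must be valid vertex indices in 1..", n)
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed")
    }
    key <- if (directed) {
      paste(edges[, 1L], edges[, 2L])
    } else {
      paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    }
    if (anyDuplicated(key)) {
      stop("duplicate edges are not allowed")
    }
  }
  if (!is.null(start)) {
    start <- as.numeric(start)
    if (length(start) != n || any(start < 0) || sum(start) <= 0) {
      stop("start weights must be length-", n,
           ", non-negative, with positive sum")
    }
  }
  structure(
    list(labels = labels, edges = edges, directed = isTRUE(directed),
         start = start, id = id),
    class = "labeled_graph"
  )
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      length(edges) == 0L) {
    return(matrix(integer(0), 0L, 2L))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must be a two-column matrix")
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  edges
}

#' @rdname labeled_graph
#' @param g a `labeled_graph`.
#' @export
n_vertices <- function(g) length(g$labels)

#' @rdname labeled_graph
#' @export
n_edges <- function(g) nrow(g$edges)

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("<labeled_graph%s: %d vertices, %d %s>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              n_vertices(x), n_edges(x),
              if (x$directed) "arcs" else "edges"))
  invisible(x)
}

#' Start distribution of the random walk
#'
#' Uniform over all vertices unless the graph carries explicit start
#' weights (as produced by [non_tottering_transform()], where walks may
#' start only on original vertices).
#'
#' @param g a `labeled_graph`.
#' @return numeric probability vector over the vertices.
#' @export
start_distribution <- function(g) {
  if (is.null(g$start)) {
    rep(1 / n_vertices(g), n_vertices(g))
  } else {
    g$start / sum(g$start)
  }
}
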