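# The circulation graph: a simple labeled digraph over an ordered vertex
# table.  Edges are directed blood flows between spaces; at most one edge
# per ordered pair and no self-loops (a binary adjacency matrix cannot hold
# parallel edges, and a space does not flow into itself).

#' Construct a circulation graph
#'
#' @param vertices A vertex table (see [vertex_table()]).
#' @param edges A two-column matrix (or data frame) of 1-based vertex index
#'   pairs, one directed edge per row: column 1 is the source, column 2 the
#'   destination.
#' @param label Condition label, e.g. `"normal heart"`.
#' @return An object of class `circulation_graph`.
#' @export
circulation_graph <- function(vertices, edges, label = "") {
  validate_vertex_table(vertices)
  edges <- as_edge_matrix(edges)
  n <- nrow(vertices)
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n))
      stop("edge endpoint out of range 1..", n)
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed")
    if (anyDuplicated(edge_keys(edges, n)))
      stop("duplicate edge: at most one edge per ordered vertex pair")
  }
  structure(list(vertices = vertices, edges = edges,
                 label = as.character(label)),
            class = "circulation_graph")
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      (is.data.frame(edges) && nrow(edges) == 0L) || !length(edges))
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  m <- as.matrix(edges)
  storage.mode(m) <- "integer"
  if (ncol(m) != 2L) stop("edges must be a two-column (from, to) matrix")
  dimnames(m) <- list(NULL, c("from", "to"))
  m
}

# Stable integer key for ordered pairs, used for set operations on edges.
edge_keys <- function(edges, n) (edges[, 1L] - 1L) * n + edges[, 2L]

#' Build the canonical normal heart
#'
#' Returns the 24-vertex directed graph of the normal circulation: caval
#' return to the right atrium, right heart to the pulmonary circulation,
#' four pulmonary veins to the left atrium, left heart to the aorta and its
#' branches, and all systemic arteries draining into the aggregate
#' target-organ vertex (SCTO), which returns blood to both venae cavae and
#' closes the circuit.  The edge set has 32 directed flows and every vertex
#' lies on a directed cycle through SCTO.
#'
#' @return A `circulation_graph` with 24 vertices and 32 edges.
#' @examples
#' nh <- build_normal_heart()
#' has_edge(nh, "RA", "RV")
#' @export
build_normal_heart <- function() {
  vt <- circulation_vertices()
  e <- rbind(
    c(1, 3),  c(2, 3),                       # caval return to RA
    c(3, 4),  c(4, 5),                       # right heart
    c(5, 6),  c(5, 7),                       # pulmonary arteries
    c(6, 8),  c(7, 9),                       # lungs
    c(8, 10), c(8, 11), c(9, 12), c(9, 13),  # pulmonary veins
    c(10, 14), c(11, 14), c(12, 14), c(13, 14),
    c(14, 15), c(15, 16),                    # left heart
    c(16, 17),                               # ascending aorta to arch
    c(17, 19), c(17, 20), c(17, 21), c(17, 18),
    c(19, 22), c(19, 23),                    # innominate branches
    c(18, 24), c(20, 24), c(21, 24), c(22, 24), c(23, 24),
    c(24, 1), c(24, 2)                       # circuit closure via SCTO
  )
  circulation_graph(vt, e, label = "normal heart")
}

#' Test for a directed edge
#'
#' @param graph A `circulation_graph`.
#' @param from,to Vertex index or abbreviation.
#' @return `TRUE` if the directed edge `from -> to` is present.
#' @export
has_edge <- function(graph, from, to) {
  stopifnot(inherits(graph, "circulation_graph"))
  i <- resolve_vertices(from, graph$vertices)
  j <- resolve_vertices(to, graph$vertices)
  n <- nrow(graph$vertices)
  any(edge_keys(graph$edges, n) == (i - 1L) * n + j)
}

#' Number of vertices / edges
#' @param graph A `circulation_graph`.
#' @return Integer count.
#' @export
n_vertices <- function(graph) nrow(graph$vertices)

#' @rdname n_vertices
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Convert a circulation graph to an igraph object
#'
#' Vertex attributes `name` (abbreviation), `full_name` and `compartment`
#' are carried over; edge direction is the direction of blood flow.
#'
#' @param x A `circulation_graph` or weighted adjacency matrix.
#' @param ... Unused.
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @export
as_igraph.circulation_graph <- function(x, ...) {
  g <- igraph::make_empty_graph(n = nrow(x$vertices), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = x$vertices$abbr)
  g <- igraph::set_vertex_attr(g, "full_name", value = x$vertices$name)
  g <- igraph::set_vertex_attr(g, "compartment",
                               value = x$vertices$compartment)
  if (nrow(x$edges))
    g <- igraph::add_edges(g, t(x$edges))
  g
}

#' @export
print.circulation_graph <- function(x, ...) {
  lbl <- if (nzchar(x$label)) x$label else "<unlabeled>"
  cat(sprintf("Circulation graph: %s\n", lbl))
  cat(sprintf("  %d vertices, %d directed edges\n",
              nrow(x$vertices), nrow(x$edges)))
  if (nrow(x$edges)) {
    ab <- x$vertices$abbr
    flows <- paste0(ab[x$edges[, 1L]], "->", ab[x$edges[, 2L]])
    cat("  flows:", paste(utils::head(flows, 8L), collapse = ", "),
        if (length(flows) > 8L) "...", "\n")
  }
  invisible(x)
}

#' @export
format.circulation_graph <- function(x, ...) {
  sprintf("<circulation_graph '%s': %d vertices, %d edges>",
          x$label, nrow(x$vertices), nrow(x$edges))
}

# Edge-set equality between two graphs over identically sized vertex tables.
graphs_equal <- function(a, b) {
  na <- nrow(a$vertices)
  if (na != nrow(b$vertices)) return(FALSE)
  setequal(edge_keys(a$edges, na), edge_keys(b$edges, na))
}
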