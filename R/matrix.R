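# Binary adjacency matrices.  Entry (i, j) is 1 when blood flows from
# vertex i to vertex j.  Rows are sources, columns destinations; the
# diagonal is identically zero and the vertex table travels with the
# matrix so indices keep their anatomical meaning.

#' Construct a binary adjacency matrix
#'
#' @param entries A square 0/1 numeric matrix, rows = source vertices,
#'   columns = destination vertices.
#' @param vertices Vertex table matching the matrix dimension; if `NULL`,
#'   dimnames of `entries` are resolved against the built-in registry.
#' @return A `binary_adjacency` object (a matrix with an attached vertex
#'   table; dimnames are the vertex abbreviations).
#' @export
binary_adjacency <- function(entries, vertices = NULL) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries))
    stop(sprintf("matrix must be square, got %d x %d",
                 nrow(entries), ncol(entries)))
  if (is.null(vertices)) {
    if (is.null(rownames(entries)))
      stop("vertex table required when the matrix has no dimnames")
    vertices <- lookup_vertices(rownames(entries))
  }
  validate_vertex_table(vertices)
  n <- nrow(vertices)
  if (nrow(entries) != n)
    stop("matrix dimension ", nrow(entries),
         " does not match vertex table length ", n)
  bad <- which(!(entries %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(entries))
    stop(sprintf("entry (%d,%d) = %s is not 0 or 1",
                 rc[1L], rc[2L], format(entries[bad[1L]])))
  }
  dg <- which(diag(entries) != 0)
  if (length(dg))
    stop(sprintf("nonzero diagonal at (%d,%d): self-loops are not allowed",
                 dg[1L], dg[1L]))
  storage.mode(entries) <- "integer"
  dimnames(entries) <- list(vertices$abbr, vertices$abbr)
  structure(entries, vertices = vertices,
            class = c("binary_adjacency", "matrix", "array"))
}

# Resolve abbreviations against the canonical + extension registries,
# registering unknown names as custom vertices with a warning.
lookup_vertices <- function(abbrs) {
  canon <- circulation_vertices()
  ext <- .extension_registry()
  name <- character(length(abbrs))
  comp <- character(length(abbrs))
  for (k in seq_along(abbrs)) {
    a <- abbrs[k]
    if (a %in% canon$abbr) {
      i <- match(a, canon$abbr)
      name[k] <- canon$name[i]; comp[k] <- canon$compartment[i]
    } else if (a %in% ext$abbr) {
      i <- match(a, ext$abbr)
      name[k] <- ext$name[i]; comp[k] <- ext$compartment[i]
    } else {
      warning("unknown vertex abbreviation '", a,
              "' registered as a custom vertex", call. = FALSE)
      name[k] <- a; comp[k] <- "other"
    }
  }
  vertex_table(abbr = abbrs, name = name, compartment = comp)
}

#' Vertex table attached to a matrix or graph
#' @param x A `binary_adjacency`, `weighted_adjacency` or
#'   `circulation_graph`.
#' @return The vertex data frame.
#' @export
vertices_of <- function(x) {
  if (inherits(x, "circulation_graph")) return(x$vertices)
  vt <- attr(x, "vertices")
  if (is.null(vt) && is.list(x)) vt <- x$vertices
  if (is.null(vt)) stop("object carries no vertex table")
  vt
}

#' Convert a circulation graph to its binary adjacency matrix
#'
#' @param graph A `circulation_graph`.
#' @return A `binary_adjacency` matrix: entry (i, j) is 1 iff the graph has
#'   the directed edge i -> j.
#' @examples
#' A <- to_binary_matrix(build_normal_heart())
#' A["RA", "RV"]
#' @export
to_binary_matrix <- function(graph) {
  stopifnot(inherits(graph, "circulation_graph"))
  n <- nrow(graph$vertices)
  m <- matrix(0L, n, n)
  if (nrow(graph$edges)) m[graph$edges] <- 1L
  binary_adjacency(m, graph$vertices)
}

#' Recover the circulation graph of a binary adjacency matrix
#'
#' Inverse of [to_binary_matrix()]: the round trip in either direction is
#' the identity.
#'
#' @param matrix A `binary_adjacency`, or any square 0/1 matrix with
#'   abbreviation dimnames.
#' @param label Condition label for the resulting graph.
#' @return A `circulation_graph`.
#' @export
from_binary_matrix <- function(matrix, label = "") {
  if (!inherits(matrix, "binary_adjacency"))
    matrix <- binary_adjacency(matrix)
  idx <- which(unclass(matrix) == 1L, arr.ind = TRUE)
  edges <- unname(idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE])
  circulation_graph(vertices_of(matrix), edges, label = label)
}

#' Interchange two columns of an adjacency matrix
#'
#' Swaps the destination columns `j` and `k` in every row, leaving rows
#' untouched: each vessel keeps its outflow connections while the origins
#' feeding the two vertices are exchanged.  Interchanging the pulmonary
#' trunk column (5) with the ascending aorta column (16) of the normal
#' heart yields the matrix of d-transposition of the great arteries;
#' applying it to a transposed heart is the arterial switch.  The operation
#' is an involution.
#'
#' @param matrix A `binary_adjacency` matrix (plain 0/1 matrices with
#'   abbreviation dimnames are coerced).
#' @param j,k 1-based column indices (or abbreviations) to interchange.
#' @return A `binary_adjacency` with columns `j` and `k` swapped.
#' @examples
#' C <- interchange_columns(to_binary_matrix(build_normal_heart()), 5, 16)
#' C["RV", "AAo"]  # ventriculoarterial discordance
#' @export
interchange_columns <- function(matrix, j, k) {
  if (!inherits(matrix, "binary_adjacency"))
    matrix <- binary_adjacency(matrix)
  vt <- vertices_of(matrix)
  j <- resolve_vertices(j, vt)
  k <- resolve_vertices(k, vt)
  m <- unclass(matrix)
  attr(m, "vertices") <- NULL
  m[, c(j, k)] <- m[, c(k, j), drop = FALSE]
  colnames(m) <- rownames(m)
  if (any(diag(m) != 0))
    stop("interchanging columns ", j, " and ", k,
         " would place an edge on the diagonal (self-loop)")
  binary_adjacency(m, vt)
}

#' @export
print.binary_adjacency <- function(x, ...) {
  vt <- vertices_of(x)
  cat(sprintf("Binary adjacency matrix: %d x %d, %d edges\n",
              nrow(x), ncol(x), sum(x)))
  print(matrix(unclass(x), nrow(x), ncol(x), dimnames = dimnames(x)))
  invisible(x)
}

# Entrywise equality after zero-padding the smaller matrix (vertex identity
# taken by index, so padding appends silent rows/columns).
matrices_equal_padded <- function(a, b) {
  hamming_distance_padded(a, b) == 0L
}

hamming_distance_padded <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  n <- max(nrow(a), nrow(b))
  pad <- function(m) {
    if (nrow(m) == n) return(m)
    out <- matrix(0L, n, n)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  sum(pad(a) != pad(b))
}
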