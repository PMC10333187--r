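# Readers and writers.  Matrix CSV: first row and first column are vertex
# abbreviations, body cells 0/1 (binary) or decimal weights.  Graph JSON
# carries the vertex table and 1-based edge pairs.  DOT and GraphML
# exports orient edges in the direction of blood flow.

#' Read an adjacency matrix from CSV
#'
#' Returns a `binary_adjacency` when every cell is 0 or 1, otherwise a
#' `weighted_adjacency` (mask = nonzero cells).  Abbreviations are resolved
#' against the built-in vertex registry; unknown abbreviations are
#' registered as custom vertices with a warning.
#'
#' @param path CSV file with a header row and a leading column of
#'   abbreviations.
#' @return A `binary_adjacency` or `weighted_adjacency`.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in '%s' is not square: %d x %d", path,
                 nrow(m), ncol(m)))
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))[1L]
    rc <- arrayInd(bad, dim(m))
    stop(sprintf("non-numeric cell at (%s, %s): '%s'",
                 rownames(m)[rc[1L]], colnames(m)[rc[2L]], m[bad]))
  }
  if (anyNA(m)) {
    rc <- arrayInd(which(is.na(m))[1L], dim(m))
    stop(sprintf("missing value at (%s, %s)",
                 rownames(m)[rc[1L]], colnames(m)[rc[2L]]))
  }
  dg <- which(diag(m) != 0)
  if (length(dg))
    stop(sprintf("nonzero diagonal at (%s, %s): self-loops are not allowed",
                 rownames(m)[dg[1L]], rownames(m)[dg[1L]]))
  if (!identical(rownames(m), colnames(m)))
    stop("row and column abbreviations differ; rows are sources and columns
 destinations of the same vertex set")
  vt <- lookup_vertices(rownames(m))
  if (all(m %in% c(0, 1))) return(binary_adjacency(m, vt))
  mask <- (m != 0) * 1L
  sub <- binary_adjacency(mask, vt)
  bw <- build_weighted_matrix(sub, measurement_table(
    source = vt$abbr[which(m != 0, arr.ind = TRUE)[, 1L]],
    destination = vt$abbr[which(m != 0, arr.ind = TRUE)[, 2L]],
    value = m[m != 0], vertices = vt))
  bw
}

#' Write an adjacency matrix to CSV
#'
#' @param matrix A `binary_adjacency` or `weighted_adjacency`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(matrix, path) {
  m <- if (inherits(matrix, "weighted_adjacency")) matrix$weights
       else unclass(matrix)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Write a circulation graph to JSON
#'
#' Schema: `{"label", "vertices": [{"index","abbr","name","compartment"}],
#' "edges": [[src, dst], ...]}` with 1-based indices.  The JSON round trip
#' is lossless.
#'
#' @param graph A `circulation_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "circulation_graph"))
  vt <- graph$vertices[, c("index", "abbr", "name", "compartment")]
  obj <- list(label = graph$label,
              vertices = vt,
              edges = unname(graph$edges))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a circulation graph from JSON
#'
#' @param path JSON file written by [write_graph_json()] (or hand-authored
#'   in the same schema).
#' @return A `circulation_graph`.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vt <- as.data.frame(obj$vertices, stringsAsFactors = FALSE)
  edges <- obj$edges
  if (is.list(edges)) edges <- do.call(rbind, edges)
  circulation_graph(vertex_table(abbr = vt$abbr, name = vt$name,
                                 compartment = vt$compartment,
                                 index = vt$index),
                    edges,
                    label = if (is.null(obj$label)) "" else obj$label)
}

#' Write a graph in DOT format
#'
#' One arc per directed blood flow, e.g. `RV -> AAo;` in transposition.
#'
#' @param graph A `circulation_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(graph, path) {
  stopifnot(inherits(graph, "circulation_graph"))
  ab <- graph$vertices$abbr
  lines <- c(sprintf('digraph "%s" {', graph$label),
             sprintf('  %s [label="%s"];', ab, ab),
             if (nrow(graph$edges))
               sprintf("  %s -> %s;", ab[graph$edges[, 1L]],
                       ab[graph$edges[, 2L]]),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a graph or weighted matrix in GraphML
#'
#' Weighted matrices carry `weight`, `metric` and `units` edge attributes.
#'
#' @param x A `circulation_graph` or `weighted_adjacency`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_graphml <- function(x, path) {
  igraph::write_graph(as_igraph(x), path, format = "graphml")
  invisible(path)
}

#' Write a graph in a chosen format
#'
#' @param x A `circulation_graph` (any format) or `weighted_adjacency`
#'   (`graphml` only).
#' @param path Output path.
#' @param format `"json"`, `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(x, path, format = c("json", "dot", "graphml")) {
  format <- match.arg(format)
  switch(format,
         json = write_graph_json(x, path),
         dot = write_graph_dot(x, path),
         graphml = write_graph_graphml(x, path))
}

#' Read / write measurement tables
#'
#' CSV columns: `source_abbr`, `dest_abbr`, `metric`, `value`, `units`,
#' `boundary_label`.
#'
#' @param path CSV path.
#' @return `read_measurements_csv`: a measurement data frame.
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_abbr", "dest_abbr", "metric", "value", "units")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("measurement CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(df$boundary_label)) df$boundary_label <- ""
  if (any(df$value < 0)) stop("measurement values must be nonnegative")
  df
}

#' @rdname read_measurements_csv
#' @param measurements A measurement data frame.
#' @export
write_measurements_csv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}
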