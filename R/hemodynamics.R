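# Weighted adjacency matrices: hemodynamic measurements (peak velocity by
# default, in cm/s) attached to the edges of a connectivity submatrix over
# the vertices of clinical interest.  The binary mask travels with the
# weights so that a zero weight on a connected edge ("unmeasured") is
# distinguishable from the absence of an edge.

#' Select a submatrix over vertices of interest
#'
#' Restricts a binary adjacency matrix to the listed vertices, in the given
#' order, preserving entries.  Typical uses: `c("RV", "PT", "RPA", "LPA")`
#' to examine the right ventricular outflow after TOF repair, or
#' `c("SVC", "RPA", "IVC", "LPA")` for a cavopulmonary (Fontan)
#' anastomosis.
#'
#' @param matrix A `binary_adjacency`.
#' @param vertices Distinct vertex indices or abbreviations.
#' @return A `binary_adjacency` over the selected vertices; the original
#'   (parent) indices are kept in the `parent_index` column of its vertex
#'   table.
#' @export
select_submatrix <- function(matrix, vertices) {
  if (!inherits(matrix, "binary_adjacency")) matrix <- binary_adjacency(matrix)
  vt <- vertices_of(matrix)
  idx <- resolve_vertices(vertices, vt)
  if (anyDuplicated(idx))
    stop("duplicate vertex in submatrix selection: ",
         paste(vt$abbr[idx[duplicated(idx)]], collapse = ", "))
  sub <- unclass(matrix)[idx, idx, drop = FALSE]
  svt <- vt[idx, , drop = FALSE]
  svt$parent_index <- svt$index
  svt$index <- seq_along(idx)
  rownames(svt) <- NULL
  binary_adjacency(sub, svt)
}

#' Assemble a measurement table
#'
#' @param source,destination Vertex abbreviations (or indices resolved
#'   against `vertices`).
#' @param value Nonnegative measurement values.
#' @param metric One of `peak_velocity`, `flow`, `pressure_gradient`.
#' @param units Measurement units (`cm/s` for peak velocity).
#' @param boundary_label Free-text description of the measurement plane,
#'   e.g. `"pulmonary valve"`.
#' @param vertices Vertex table used to resolve abbreviations (default
#'   canonical).
#' @return A `data.frame` with columns `source_abbr`, `dest_abbr`,
#'   `metric`, `value`, `units`, `boundary_label`.
#' @export
measurement_table <- function(source, destination, value,
                              metric = "peak_velocity", units = "cm/s",
                              boundary_label = "",
                              vertices = circulation_vertices()) {
  metric <- match.arg(metric, c("peak_velocity", "flow", "pressure_gradient"))
  if (any(value < 0)) stop("measurement values must be nonnegative")
  to_abbr <- function(x) {
    if (is.character(x)) return(x)
    vertices$abbr[resolve_vertices(x, vertices)]
  }
  data.frame(source_abbr = to_abbr(source), dest_abbr = to_abbr(destination),
             metric = metric, value = as.numeric(value), units = units,
             boundary_label = boundary_label, stringsAsFactors = FALSE)
}

#' Combine a connectivity submatrix with hemodynamic measurements
#'
#' Places each measured value at its edge's cell; connected but unmeasured
#' cells stay 0 and are listed in the `unmeasured` field, so a zero weight
#' is never ambiguous between "no edge" and "no data".
#'
#' @param submatrix A `binary_adjacency` (typically from
#'   [select_submatrix()]).
#' @param measurements A measurement table (see [measurement_table()] /
#'   [read_measurements_csv()]); endpoints are matched by abbreviation
#'   against the submatrix vertex table.  All rows must share one metric.
#' @return A `weighted_adjacency`: list with `weights` (numeric matrix),
#'   `mask` (the connectivity submatrix), `vertices`, `metric`, `units`,
#'   `unmeasured` (data frame of connected, unmeasured edges).
#' @export
build_weighted_matrix <- function(submatrix, measurements) {
  if (!inherits(submatrix, "binary_adjacency"))
    submatrix <- binary_adjacency(submatrix)
  vt <- vertices_of(submatrix)
  mask <- unclass(submatrix)
  w <- matrix(0, nrow(mask), ncol(mask), dimnames = dimnames(mask))

  metric <- "peak_velocity"; units <- "cm/s"
  if (nrow(measurements)) {
    metric <- unique(measurements$metric)
    if (length(metric) != 1L)
      stop("one metric per weighted matrix; got: ",
           paste(metric, collapse = ", "))
    units <- unique(measurements$units)[1L]
    seen <- character(0)
    for (r in seq_len(nrow(measurements))) {
      i <- match(measurements$source_abbr[r], vt$abbr)
      j <- match(measurements$dest_abbr[r], vt$abbr)
      if (is.na(i) || is.na(j))
        stop(sprintf("measurement %s -> %s references a vertex outside the submatrix",
                     measurements$source_abbr[r], measurements$dest_abbr[r]))
      if (mask[i, j] != 1L)
        stop(sprintf("measurement on %s -> %s but the submatrix has no such edge",
                     vt$abbr[i], vt$abbr[j]))
      key <- paste0(i, ",", j)
      if (key %in% seen)
        stop(sprintf("duplicate measurement for edge %s -> %s",
                     vt$abbr[i], vt$abbr[j]))
      seen <- c(seen, key)
      if (measurements$value[r] < 0) stop("measurement values must be nonnegative")
      w[i, j] <- measurements$value[r]
    }
  }

  unm <- which(mask == 1L & w == 0, arr.ind = TRUE)
  unmeasured <- data.frame(source_abbr = vt$abbr[unm[, 1L]],
                           dest_abbr = vt$abbr[unm[, 2L]],
                           stringsAsFactors = FALSE)
  structure(list(weights = w, mask = mask, vertices = vt,
                 metric = metric, units = units, unmeasured = unmeasured),
            class = "weighted_adjacency")
}

#' @export
print.weighted_adjacency <- function(x, ...) {
  cat(sprintf("Weighted adjacency matrix (%s, %s): %d x %d\n",
              x$metric, x$units, nrow(x$weights), ncol(x$weights)))
  print(x$weights)
  if (nrow(x$unmeasured))
    cat("  unmeasured edges:",
        paste(x$unmeasured$source_abbr, "->", x$unmeasured$dest_abbr,
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_igraph.weighted_adjacency <- function(x, ...) {
  g <- igraph::graph_from_adjacency_matrix(x$mask, mode = "directed")
  g <- igraph::set_vertex_attr(g, "full_name", value = x$vertices$name)
  g <- igraph::set_vertex_attr(g, "compartment", value = x$vertices$compartment)
  el <- igraph::as_edgelist(g, names = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = x$weights[el])
  g <- igraph::set_edge_attr(g, "metric", value = x$metric)
  g <- igraph::set_edge_attr(g, "units", value = x$units)
  g
}

# default normal peak-velocity ranges (cm/s) by source compartment
.default_velocity_ranges <- function() {
  list(ventricle = c(80, 120),
       great_artery = c(60, 100),
       pulmonary_artery = c(60, 100),
       systemic_vein = c(20, 60),
       other = c(30, 90))
}

#' Generate synthetic hemodynamic measurements
#'
#' Emulates peak-velocity measurements at the boundaries between connected
#' spaces (the kind of values read off time-resolved phase-contrast flow
#' imaging).  Baseline velocities are drawn uniformly from a normal range
#' chosen by the source vertex's compartment (defaults: ventricular outflow
#' 80-120 cm/s, pulmonary branches 60-100 cm/s, caval flow 20-60 cm/s);
#' edges listed as stenotic are multiplied by `stenosis_factor`.
#' Deterministic for a fixed seed.
#'
#' @param graph A `circulation_graph`.
#' @param edges Two-column matrix of vertex index pairs to measure; default
#'   all edges of the graph.
#' @param condition `"normal"` or `"stenosis"`; under `"normal"` the
#'   stenotic list is ignored.
#' @param stenotic_edges Two-column matrix of edges with simulated stenosis
#'   (must be among `edges`).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param stenosis_factor Multiplier applied to stenotic edges (default
#'   2.5).
#' @param ranges Named list of `c(lo, hi)` normal ranges per source
#'   compartment, merged over the defaults.
#' @return A measurement table (see [measurement_table()]).
#' @examples
#' m <- generate_synthetic_measurements(build_normal_heart(),
#'   edges = rbind(c(4, 5), c(5, 6), c(5, 7)), seed = 1)
#' @export
generate_synthetic_measurements <- function(graph, edges = NULL,
                                            condition = c("normal", "stenosis"),
                                            stenotic_edges = NULL,
                                            seed = 1L,
                                            stenosis_factor = 2.5,
                                            ranges = list()) {
  stopifnot(inherits(graph, "circulation_graph"))
  condition <- match.arg(condition)
  vt <- graph$vertices
  if (is.null(edges)) edges <- graph$edges
  edges <- as_edge_matrix(edges)
  n <- nrow(vt)
  gk <- edge_keys(graph$edges, n)
  ek <- edge_keys(edges, n)
  if (!all(ek %in% gk)) {
    bad <- which(!(ek %in% gk))[1L]
    stop(sprintf("edge %s -> %s is not in the graph",
                 vt$abbr[edges[bad, 1L]], vt$abbr[edges[bad, 2L]]))
  }
  rng <- utils::modifyList(.default_velocity_ranges(), ranges)
  lohi <- t(vapply(seq_len(nrow(edges)), function(r) {
    comp <- vt$compartment[edges[r, 1L]]
    if (!is.null(rng[[comp]])) rng[[comp]] else rng$other
  }, numeric(2)))

  vals <- with_preserved_rng(seed, {
    stats::runif(nrow(edges), lohi[, 1L], lohi[, 2L])
  })

  if (condition == "stenosis" && !is.null(stenotic_edges)) {
    stenotic_edges <- as_edge_matrix(stenotic_edges)
    sk <- edge_keys(stenotic_edges, n)
    if (!all(sk %in% ek))
      stop("stenotic edges must be among the measured edges")
    vals[ek %in% sk] <- vals[ek %in% sk] * stenosis_factor
  }

  measurement_table(
    source = vt$abbr[edges[, 1L]], destination = vt$abbr[edges[, 2L]],
    value = vals,
    boundary_label = paste(vt$abbr[edges[, 1L]], vt$abbr[edges[, 2L]],
                           sep = "-"),
    vertices = vt)
}

# Run expr under set.seed(seed) without disturbing the caller's RNG.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
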