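# Physiological analysis: reachability, the two-path survival rule,
# five-category classification of structural differences, and diagnosis by
# matrix matching against the catalog.

#' Directed reachability between two vertices
#'
#' `reachable(g, v, v)` is `TRUE` (the empty path).
#'
#' @param graph A `circulation_graph`.
#' @param source,target Vertex index or abbreviation.
#' @return Logical: does a directed path `source -> ... -> target` exist?
#' @export
reachable <- function(graph, source, target) {
  stopifnot(inherits(graph, "circulation_graph"))
  i <- resolve_vertices(source, graph$vertices)
  j <- resolve_vertices(target, graph$vertices)
  if (i == j) return(TRUE)
  g <- as_igraph(graph)
  is.finite(igraph::distances(g, v = i, to = j, mode = "out")[1L, 1L])
}

#' Check the two-path survival rule
#'
#' A circulation is viable when there exists a lung such that (a) some
#' systemic venous source reaches that lung and (b) that lung reaches the
#' systemic arterial supply.  Blood must be able to return from the body,
#' undergo gas exchange, and be pumped back out; a heart in which the
#' systemic venous return is pumped straight back to the aorta without
#' traversing a lung (e.g. ventriculoarterial discordance without a septal
#' defect) fails the rule.  Connectivity only is checked; adequacy of
#' mixing and other physiological factors are out of scope.
#'
#' @param graph A `circulation_graph`.
#' @param venous_sources Vertex indices of the systemic venous return
#'   (default SVC = 1, IVC = 2).
#' @param lungs Vertex indices of the lungs (default RL = 8, LL = 9).
#' @param arterial_target Vertex index of the systemic arterial supply
#'   (default AAo = 16; a relabeled vertex 16, e.g. a common trunk, still
#'   counts by index).
#' @param require_full_circuit If `TRUE`, additionally require the arterial
#'   target to reach some venous source (closure of the systemic loop);
#'   the classical rule checks only the two paths, so this is off by
#'   default.
#' @return A `chd_viability` report: `viable`, `qualifying_lungs`, and for
#'   each qualifying lung a witness venous path and arterial path (index
#'   sequences).
#' @examples
#' check_survival(build_normal_heart())$viable
#' @export
check_survival <- function(graph, venous_sources = c(1L, 2L),
                           lungs = c(8L, 9L), arterial_target = 16L,
                           require_full_circuit = FALSE) {
  stopifnot(inherits(graph, "circulation_graph"))
  vt <- graph$vertices
  venous_sources <- resolve_vertices(venous_sources, vt)
  lungs <- resolve_vertices(lungs, vt)
  arterial_target <- resolve_vertices(arterial_target, vt)

  g <- as_igraph(graph)
  dist_from_src <- igraph::distances(g, v = venous_sources, mode = "out")
  dist_from_lung <- igraph::distances(g, v = lungs, mode = "out")

  qualifying <- integer(0)
  witness <- list()
  for (li in seq_along(lungs)) {
    L <- lungs[li]
    src_ok <- which(is.finite(dist_from_src[, L]))
    art_ok <- is.finite(dist_from_lung[li, arterial_target])
    if (length(src_ok) && art_ok) {
      s <- venous_sources[src_ok[1L]]
      vp <- igraph::shortest_paths(g, from = s, to = L,
                                   mode = "out")$vpath[[1L]]
      ap <- igraph::shortest_paths(g, from = L, to = arterial_target,
                                   mode = "out")$vpath[[1L]]
      qualifying <- c(qualifying, L)
      witness[[vt$abbr[L]]] <- list(venous_path = as.integer(vp),
                                    arterial_path = as.integer(ap))
    }
  }

  viable <- length(qualifying) > 0L
  if (viable && require_full_circuit) {
    back <- igraph::distances(g, v = arterial_target, mode = "out")
    if (!any(is.finite(back[1L, venous_sources]))) viable <- FALSE
  }

  structure(list(viable = viable,
                 qualifying_lungs = qualifying,
                 venous_sources_checked = venous_sources,
                 arterial_target = arterial_target,
                 witness_paths = witness,
                 label = graph$label),
            class = "chd_viability")
}

#' @export
print.chd_viability <- function(x, ...) {
  cat(sprintf("Survival-rule check: %s\n",
              if (nzchar(x$label)) x$label else "<unlabeled>"))
  cat(sprintf("  viable: %s\n", x$viable))
  if (length(x$qualifying_lungs))
    cat("  qualifying lungs:", paste(names(x$witness_paths), collapse = ", "),
        "\n")
  for (nm in names(x$witness_paths)) {
    w <- x$witness_paths[[nm]]
    cat(sprintf("  %s: venous path %s; arterial path %s\n", nm,
                paste(w$venous_path, collapse = "->"),
                paste(w$arterial_path, collapse = "->")))
  }
  invisible(x)
}

# ---- structural diff --------------------------------------------------------

#' Classify the structural differences between two hearts
#'
#' Compares two binary adjacency matrices element-wise and assigns the
#' differences to the five structural categories: increased vertices,
#' decreased vertices (a shared vertex stripped of all its edges),
#' increased edges, decreased edges, and abnormal connections.  An
#' abnormal connection (rewiring) is a removed edge paired with an added
#' edge sharing its source (or sharing its destination with a changed
#' source): the flow was not simply gained or lost but redirected, as in
#' ventriculoarterial discordance.  Edges incident to added vertices are
#' attributed to the vertex addition, and edges lost by an isolated vertex
#' to the isolation, rather than counted as independent edge changes.
#'
#' @param reference,variant `binary_adjacency` matrices; the reference
#'   vertex table must be a prefix of the variant's (by index; extra
#'   variant vertices allowed, relabels reported).
#' @return A `chd_diff` report with `added_vertices`, `isolated_vertices`,
#'   `relabeled_vertices`, `added_edges`, `removed_edges`, `rewirings` and
#'   `categories`.
#' @examples
#' nh <- to_binary_matrix(build_normal_heart())
#' pda <- to_binary_matrix(build_condition("PDA"))
#' classify_diff(nh, pda)$categories
#' @export
classify_diff <- function(reference, variant) {
  if (!inherits(reference, "binary_adjacency"))
    reference <- binary_adjacency(reference)
  if (!inherits(variant, "binary_adjacency"))
    variant <- binary_adjacency(variant)
  vr <- vertices_of(reference); vv <- vertices_of(variant)
  nr <- nrow(vr); nv <- nrow(vv)
  if (nr > nv)
    stop("reference has more vertices (", nr, ") than variant (", nv, ")")

  R <- matrix(0L, nv, nv)
  R[seq_len(nr), seq_len(nr)] <- unclass(reference)
  V <- unclass(variant)

  added_idx <- which(R == 0L & V == 1L, arr.ind = TRUE)
  removed_idx <- which(R == 1L & V == 0L, arr.ind = TRUE)
  added <- unname(added_idx[order(added_idx[, 1L], added_idx[, 2L]), ,
                            drop = FALSE])
  removed <- unname(removed_idx[order(removed_idx[, 1L], removed_idx[, 2L]), ,
                                drop = FALSE])

  added_vertices <- vv[vv$index > nr, , drop = FALSE]
  relabeled <- which(vr$abbr != vv$abbr[seq_len(nr)])

  # a shared vertex with edges in the reference and none in the variant
  deg_ref <- rowSums(R) + colSums(R)
  deg_var <- rowSums(V) + colSums(V)
  isolated <- as.integer(which(seq_len(nv) <= nr & deg_ref > 0 & deg_var == 0))

  new_vtx <- added_vertices$index
  a_vertex <- (added[, 1L] %in% new_vtx) | (added[, 2L] %in% new_vtx)
  r_vertex <- (removed[, 1L] %in% isolated) | (removed[, 2L] %in% isolated)

  # pair removed/added edges into rewirings (shared source, then shared
  # destination), over edges not already explained by vertex changes
  a_free <- which(!a_vertex)
  r_free <- which(!r_vertex)
  a_used <- rep(FALSE, nrow(added))
  rewirings <- list()
  r_rewired <- rep(FALSE, nrow(removed))
  for (ri in r_free) {
    i <- removed[ri, 1L]; j <- removed[ri, 2L]
    cand <- a_free[!a_used[a_free] & added[a_free, 1L] == i]
    pivot <- i
    if (!length(cand)) {
      cand <- a_free[!a_used[a_free] & added[a_free, 2L] == j]
      pivot <- j
    }
    if (length(cand)) {
      ai <- cand[1L]
      a_used[ai] <- TRUE
      r_rewired[ri] <- TRUE
      rewirings <- c(rewirings, list(list(
        vertex = pivot,
        removed = removed[ri, ], added = added[ai, ])))
    }
  }

  leftover_added <- added[!a_vertex & !a_used, , drop = FALSE]
  leftover_removed <- removed[!r_vertex & !r_rewired, , drop = FALSE]

  categories <- character(0)
  if (nrow(added_vertices)) categories <- c(categories, "increased_vertices")
  if (length(isolated)) categories <- c(categories, "decreased_vertices")
  if (nrow(leftover_added)) categories <- c(categories, "increased_edges")
  if (nrow(leftover_removed)) categories <- c(categories, "decreased_edges")
  if (length(rewirings)) categories <- c(categories, "abnormal_connections")

  structure(list(added_vertices = added_vertices,
                 isolated_vertices = isolated,
                 relabeled_vertices = relabeled,
                 added_edges = added,
                 removed_edges = removed,
                 rewirings = rewirings,
                 categories = categories,
                 vertex_table = vv),
            class = "chd_diff")
}

#' @export
print.chd_diff <- function(x, ...) {
  ab <- x$vertex_table$abbr
  fmt <- function(e) if (!nrow(e)) "none" else
    paste(ab[e[, 1L]], "->", ab[e[, 2L]], collapse = ", ")
  cat("Structural diff\n")
  cat("  categories:",
      if (length(x$categories)) paste(x$categories, collapse = ", ")
      else "none (identical)", "\n")
  if (nrow(x$added_vertices))
    cat("  added vertices:", paste(x$added_vertices$abbr, collapse = ", "), "\n")
  if (length(x$isolated_vertices))
    cat("  isolated vertices:", paste(ab[x$isolated_vertices], collapse = ", "),
        "\n")
  if (length(x$relabeled_vertices))
    cat("  relabeled vertices:", paste(ab[x$relabeled_vertices], collapse = ", "),
        "\n")
  cat("  added edges:", fmt(x$added_edges), "\n")
  cat("  removed edges:", fmt(x$removed_edges), "\n")
  for (rw in x$rewirings)
    cat(sprintf("  rewiring at %s: %s->%s replaced by %s->%s\n",
                ab[rw$vertex], ab[rw$removed[1L]], ab[rw$removed[2L]],
                ab[rw$added[1L]], ab[rw$added[2L]]))
  invisible(x)
}

#' Detect anomalous pulmonary venous return
#'
#' Implements the defining quantifier literally: for some pulmonary-vein
#' vertex i in {10, 11, 12, 13} there exists a destination j other than the
#' left atrium (14) with entry (i, j) = 1.
#'
#' @param matrix A `binary_adjacency` of at least 14 vertices.
#' @return Logical.
#' @export
has_anomalous_pulmonary_venous_return <- function(matrix) {
  if (!inherits(matrix, "binary_adjacency")) matrix <- binary_adjacency(matrix)
  m <- unclass(matrix)
  if (nrow(m) < 14L)
    stop("matrix must cover at least the 14 canonical vertices up to the LA")
  any(m[10:13, -14L] == 1L)
}

# ---- diagnosis --------------------------------------------------------------

#' Element-wise Hamming distance between adjacency matrices
#'
#' Matrices of unequal dimension are zero-padded to the larger size before
#' comparison (vertex identity by index).
#'
#' @param a,b Binary adjacency matrices.
#' @return Integer count of differing cells.
#' @export
hamming_distance <- function(a, b) hamming_distance_padded(a, b)

#' Reference catalog of condition matrices for diagnosis
#'
#' Builds, from the normal heart, the binary adjacency matrix of every
#' cataloged disease (including the directional/sided variants of
#' parameterized conditions) plus the classic compound conditions
#' (d-TGA with a VSD, extreme TOF with and without a right mBT shunt, and
#' the cavopulmonary Fontan circulation).
#'
#' @return Named list of `binary_adjacency` matrices, including
#'   `"normal heart"`.
#' @export
build_condition_catalog <- function() {
  out <- list("normal heart" = to_binary_matrix(build_normal_heart()))
  add <- function(name, trans) {
    g <- apply_transformation(build_normal_heart(), trans)
    out[[name]] <<- to_binary_matrix(g)
  }
  for (nm in disease_names()) {
    tpl <- default_catalog()$diseases[[nm]]
    pspec <- tpl$parameters
    variant_sets <- list(list())
    # expand choice-constrained parameters into variants
    for (p in names(pspec)) {
      ch <- unlist(pspec[[p]]$choices)
      if (is.null(ch)) next
      variant_sets <- do.call(c, lapply(ch, function(v) {
        lapply(variant_sets, function(vs) c(vs, stats::setNames(list(v), p)))
      }))
    }
    for (vs in variant_sets) {
      label <- if (length(vs))
        sprintf("%s (%s)", nm, paste(unlist(vs), collapse = ", ")) else nm
      add(label, get_disease(nm, vs))
    }
  }
  add("d-TGA with VSD",
      compose_transformations(get_disease("d-TGA"), get_disease("VSD")))
  add("extreme TOF", extreme_tof())
  add("extreme TOF with right mBT shunt",
      compose_transformations(extreme_tof(), get_procedure("right_mBT_shunt")))
  add("Fontan circulation",
      compose_transformations(get_procedure("bidirectional_glenn"),
                              get_procedure("fontan")))
  out
}

#' Diagnose a heart by matrix matching
#'
#' Ranks every catalog condition by element-wise Hamming distance between
#' its matrix (built from the normal heart) and the input; distance 0 is an
#' exact diagnosis.
#'
#' @param matrix A `binary_adjacency` (e.g. from [read_matrix_csv()]).
#' @param catalog Named list of condition matrices; defaults to
#'   [build_condition_catalog()].
#' @return A `chd_diagnosis` data frame (`condition`, `distance`) sorted by
#'   ascending distance, with per-condition residual diff reports in
#'   `attr(, "residuals")`.
#' @examples
#' dx <- diagnose(to_binary_matrix(build_condition("tricuspid_atresia")))
#' head(dx, 3)
#' @export
diagnose <- function(matrix, catalog = NULL) {
  if (!inherits(matrix, "binary_adjacency")) matrix <- binary_adjacency(matrix)
  if (is.null(catalog)) catalog <- build_condition_catalog()
  stopifnot(length(catalog) > 0L, !is.null(names(catalog)))
  d <- vapply(catalog, hamming_distance, integer(1), b = matrix)
  ord <- order(d, names(catalog))
  res <- data.frame(condition = names(catalog)[ord],
                    distance = unname(d[ord]),
                    row.names = NULL, stringsAsFactors = FALSE)
  residuals <- lapply(catalog[ord], function(ref) {
    vr <- vertices_of(ref)
    inp <- matrix
    if (nrow(vr) > nrow(vertices_of(inp))) {
      # pad the input with the catalog's extra vertices so the report can
      # name what the input is missing
      m <- base::matrix(0L, nrow(vr), nrow(vr))
      m[seq_len(nrow(inp)), seq_len(ncol(inp))] <- unclass(inp)
      vt <- vertices_of(inp)
      extra <- vr[(nrow(vt) + 1L):nrow(vr), , drop = FALSE]
      inp <- binary_adjacency(m, rbind(vt, extra))
    }
    classify_diff(ref, inp)
  })
  structure(res, residuals = residuals, class = c("chd_diagnosis",
                                                  "data.frame"))
}

#' @export
print.chd_diagnosis <- function(x, n = 5L, ...) {
  cat("Diagnosis by catalog matching (top", min(n, nrow(x)), "of",
      nrow(x), "conditions)\n")
  print.data.frame(utils::head(x, n))
  if (x$distance[1L] == 0L)
    cat("exact match:", x$condition[1L], "\n")
  invisible(x)
}
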