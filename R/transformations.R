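# Disease and procedure transformations.
#
# A transformation is an ordered edit script over a circulation graph:
# add_vertex, add_edge, remove_edge, isolate_vertex, relabel_vertex and
# interchange_columns steps.  The shipped catalog transcribes the standard
# manifestations of common CHDs and palliative/corrective procedures; it
# is stored as YAML so that users can register further conditions in the
# same schema.

.edit_kinds <- c("add_vertex", "add_edge", "remove_edge", "isolate_vertex",
                 "relabel_vertex", "interchange_columns")

.categories <- c("increased_vertices", "decreased_vertices",
                 "increased_edges", "decreased_edges",
                 "abnormal_connections", "procedure", "composite")

#' Construct a single edit step
#'
#' @param kind One of `add_vertex`, `add_edge`, `remove_edge`,
#'   `isolate_vertex`, `relabel_vertex`, `interchange_columns`.
#' @param ... Kind-specific payload: `from`/`to` for edge steps (`to = "new"`
#'   refers to the vertex created by the preceding `add_vertex`), `abbr`,
#'   `name`, `compartment` for `add_vertex`, `index` (+ new `abbr`/`name`)
#'   for `relabel_vertex` and `isolate_vertex`, `j`/`k` for
#'   `interchange_columns`.
#' @return An `edit_step` object.
#' @export
edit_step <- function(kind, ...) {
  kind <- match.arg(kind, .edit_kinds)
  step <- c(list(kind = kind), list(...))
  need <- switch(kind,
    add_vertex = "abbr",
    add_edge = c("from", "to"),
    remove_edge = c("from", "to"),
    isolate_vertex = "index",
    relabel_vertex = "index",
    interchange_columns = c("j", "k"))
  missing <- setdiff(need, names(step))
  if (length(missing))
    stop(kind, " step is missing field(s): ", paste(missing, collapse = ", "))
  structure(step, class = "edit_step")
}

#' Construct a transformation
#'
#' @param name Human-readable condition or procedure name.
#' @param category One of the five structural disease categories,
#'   `procedure`, or `composite`.
#' @param steps List of [edit_step()]s, applied in order.
#' @param parameters Named list of resolved parameter values (metadata).
#' @param asserts Optional list of cells `list(i =, j =, value =)` whose
#'   values are checked (not edited) after application.
#' @return A `chd_transformation`.
#' @export
transformation <- function(name, category, steps, parameters = list(),
                           asserts = list()) {
  category <- match.arg(category, .categories)
  stopifnot(is.list(steps))
  steps <- lapply(steps, function(s) {
    if (!inherits(s, "edit_step")) s <- do.call(edit_step, s)
    s
  })
  structure(list(name = name, category = category, steps = steps,
                 parameters = parameters, asserts = asserts),
            class = "chd_transformation")
}

#' @export
print.chd_transformation <- function(x, ...) {
  cat(sprintf("Transformation: %s [%s], %d step(s)\n",
              x$name, x$category, length(x$steps)))
  for (s in x$steps) {
    desc <- switch(s$kind,
      add_vertex = sprintf("add vertex %s", s$abbr),
      add_edge = sprintf("add edge %s -> %s", s$from, s$to),
      remove_edge = sprintf("remove edge %s -> %s", s$from, s$to),
      isolate_vertex = sprintf("isolate vertex %s", s$index),
      relabel_vertex = sprintf("relabel vertex %s as %s", s$index, s$abbr),
      interchange_columns = sprintf("interchange columns %s and %s", s$j, s$k))
    cat("  -", desc, "\n")
  }
  if (length(x$parameters))
    cat("  parameters:",
        paste(names(x$parameters), unlist(x$parameters), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

# ---- catalog loading --------------------------------------------------------

.chd_env <- new.env(parent = emptyenv())

#' Load a transformation catalog from YAML
#'
#' @param path Path to a catalog file; defaults to the catalog shipped with
#'   the package.
#' @return A list with `diseases` and `procedures`, each a named list of
#'   raw catalog templates (instantiate with [get_disease()] /
#'   [get_procedure()]).
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "catalog.yaml", package = "chdgraph",
                        mustWork = TRUE)
  cat_raw <- yaml::read_yaml(path)
  if (!all(c("diseases", "procedures") %in% names(cat_raw)))
    stop("catalog file must contain 'diseases' and 'procedures' sections")
  cat_raw
}

default_catalog <- function() {
  if (is.null(.chd_env$catalog)) .chd_env$catalog <- load_catalog()
  .chd_env$catalog
}

#' Names of cataloged diseases and procedures
#' @return Character vector of catalog keys.
#' @export
disease_names <- function() names(default_catalog()$diseases)

#' @rdname disease_names
#' @export
procedure_names <- function() names(default_catalog()$procedures)

# Instantiate a catalog template: resolve parameters, filter `when`
# clauses, substitute "$param" endpoints.
instantiate_template <- function(name, tpl, parameters) {
  spec <- tpl$parameters
  vals <- list()
  for (p in names(spec)) {
    v <- if (!is.null(parameters[[p]])) parameters[[p]] else spec[[p]]$default
    if (!is.null(spec[[p]]$choices) && !(v %in% unlist(spec[[p]]$choices)))
      stop(sprintf("invalid value '%s' for parameter '%s' of %s (choose from: %s)",
                   v, p, name, paste(unlist(spec[[p]]$choices), collapse = ", ")))
    if (!is.null(spec[[p]]$forbid) && v %in% unlist(spec[[p]]$forbid))
      stop(sprintf("value '%s' is not allowed for parameter '%s' of %s",
                   v, p, name))
    vals[[p]] <- v
  }
  extra <- setdiff(names(parameters), names(spec))
  if (length(extra))
    stop(name, " does not take parameter(s): ", paste(extra, collapse = ", "))
  subst <- function(x) {
    if (is.character(x) && length(x) == 1L && startsWith(x, "$")) {
      p <- substring(x, 2L)
      if (is.null(vals[[p]])) stop("unresolved parameter reference ", x)
      return(vals[[p]])
    }
    x
  }
  steps <- list()
  for (s in tpl$steps) {
    if (!is.null(s$when)) {
      keep <- all(vapply(names(s$when), function(p) {
        vals[[p]] %in% unlist(s$when[[p]])
      }, logical(1)))
      if (!keep) next
      s$when <- NULL
    }
    steps <- c(steps, list(tpl_step_to_edit(s, subst)))
  }
  transformation(name = name, category = tpl$category, steps = steps,
                 parameters = vals,
                 asserts = if (is.null(tpl$asserts)) list() else tpl$asserts)
}

tpl_step_to_edit <- function(s, subst) {
  kind <- s$op
  payload <- s[setdiff(names(s), "op")]
  payload <- lapply(payload, subst)
  do.call(edit_step, c(list(kind = kind), payload))
}

#' Retrieve a disease transformation from the catalog
#'
#' @param name Catalog key, e.g. `"PDA"`, `"VSD"`, `"d-TGA"`; see
#'   [disease_names()].
#' @param parameters Named list overriding parameter defaults, e.g.
#'   `list(direction = "left_to_right")` for septal defects,
#'   `list(lung = "left")` for MAPCA, `list(vein = 12, target = 1)` for
#'   anomalous pulmonary venous return.
#' @return A `chd_transformation`.
#' @examples
#' get_disease("PDA")
#' get_disease("VSD", parameters = list(direction = "right_to_left"))
#' @export
get_disease <- function(name, parameters = list()) {
  cat_d <- default_catalog()$diseases
  if (!name %in% names(cat_d))
    stop("unknown disease '", name, "'; catalog holds: ",
         paste(names(cat_d), collapse = ", "))
  instantiate_template(name, cat_d[[name]], parameters)
}

#' Retrieve a procedure transformation from the catalog
#'
#' @param name Catalog key, e.g. `"fontan"`; see [procedure_names()].
#' @return A `chd_transformation`.
#' @examples
#' get_procedure("bidirectional_glenn")
#' @export
get_procedure <- function(name) {
  cat_p <- default_catalog()$procedures
  if (!name %in% names(cat_p))
    stop("unknown procedure '", name, "'; catalog holds: ",
         paste(names(cat_p), collapse = ", "))
  instantiate_template(name, cat_p[[name]], list())
}

#' The extreme tetralogy of Fallot composite
#'
#' Extreme TOF is modeled as a bidirectional ventricular septal defect plus
#' pulmonary atresia, with the flow in the pulmonary trunk to right
#' pulmonary artery segment reversed (the trunk is filled retrogradely once
#' antegrade flow is lost and shunt-supplied flow arrives via the RPA).
#' Apply [get_procedure("right_mBT_shunt")][get_procedure] afterwards for
#' the palliated anatomy.
#'
#' @return A composite `chd_transformation`.
#' @export
extreme_tof <- function() {
  rev_pt_rpa <- transformation(
    "reversed PT-RPA flow", "composite",
    steps = list(edit_step("remove_edge", from = 5, to = 6),
                 edit_step("add_edge", from = 6, to = 5)))
  t <- compose_transformations(get_disease("VSD"),
                               get_disease("pulmonary_atresia"),
                               rev_pt_rpa)
  t$name <- "extreme TOF"
  t
}

# ---- application engine -----------------------------------------------------

#' Apply a transformation to a circulation graph
#'
#' The input graph is never modified; a new graph is returned with the
#' transformation's name appended to its label.  In strict mode (default)
#' removing an absent edge or adding an existing one is an error; in
#' lenient mode such steps are skipped with a warning.
#'
#' @param graph A `circulation_graph`.
#' @param transform A `chd_transformation`.
#' @param strict Logical; error (`TRUE`) or warn-and-skip (`FALSE`) on
#'   inapplicable steps.
#' @return The transformed `circulation_graph`.
#' @examples
#' dtga <- apply_transformation(build_normal_heart(), get_disease("d-TGA"))
#' has_edge(dtga, "RV", "AAo")
#' @export
apply_transformation <- function(graph, transform, strict = TRUE) {
  stopifnot(inherits(graph, "circulation_graph"),
            inherits(transform, "chd_transformation"))
  vt <- graph$vertices
  edges <- graph$edges
  last_new <- NA_integer_

  res_idx <- function(x) {
    if (identical(x, "new")) {
      if (is.na(last_new)) stop("'new' used before any add_vertex step")
      return(last_new)
    }
    resolve_vertices(x, vt)
  }
  complain <- function(msg) {
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    FALSE
  }
  has <- function(i, j) any(edges[, 1L] == i & edges[, 2L] == j)

  for (s in transform$steps) {
    switch(s$kind,
      add_vertex = {
        abbr <- s$abbr
        if (abbr %in% vt$abbr) {
          if (strict) stop("add_vertex: abbreviation '", abbr,
                           "' already present", call. = FALSE)
          abbr <- make.unique(c(vt$abbr, abbr))[nrow(vt) + 1L]
        }
        vt <- rbind(vt, data.frame(
          index = nrow(vt) + 1L, abbr = abbr,
          name = if (is.null(s$name)) abbr else s$name,
          compartment = if (is.null(s$compartment)) "other" else s$compartment,
          stringsAsFactors = FALSE))
        last_new <- nrow(vt)
      },
      add_edge = {
        i <- res_idx(s$from); j <- res_idx(s$to)
        if (i == j) stop("add_edge: self-loop ", i, " -> ", j, call. = FALSE)
        if (has(i, j)) {
          complain(sprintf("add_edge (%d,%d): edge already present", i, j))
        } else edges <- rbind(edges, c(i, j))
      },
      remove_edge = {
        i <- res_idx(s$from); j <- res_idx(s$to)
        if (!has(i, j)) {
          complain(sprintf("remove_edge (%d,%d): edge not present", i, j))
        } else edges <- edges[!(edges[, 1L] == i & edges[, 2L] == j), ,
                              drop = FALSE]
      },
      isolate_vertex = {
        v <- res_idx(s$index)
        edges <- edges[edges[, 1L] != v & edges[, 2L] != v, , drop = FALSE]
      },
      relabel_vertex = {
        v <- res_idx(s$index)
        if (!is.null(s$abbr)) vt$abbr[v] <- s$abbr
        if (!is.null(s$name)) vt$name[v] <- s$name
        if (!is.null(s$compartment)) vt$compartment[v] <- s$compartment
      },
      interchange_columns = {
        j <- res_idx(s$j); k <- res_idx(s$k)
        if (j != k) {
          if (has(j, k) || has(k, j))
            stop(sprintf(paste0("interchange_columns (%d,%d): an edge ",
                                "between the two columns would land on ",
                                "the diagonal"), j, k), call. = FALSE)
          in_j <- edges[, 2L] == j
          in_k <- edges[, 2L] == k
          edges[in_j, 2L] <- k
          edges[in_k, 2L] <- j
        }
      }
    )
  }

  lbl <- if (nzchar(graph$label)) paste(graph$label, transform$name,
                                        sep = " + ") else transform$name
  out <- circulation_graph(vt, edges, label = lbl)

  for (a in transform$asserts) {
    actual <- as.integer(has_edge(out, a$i, a$j))
    if (actual != a$value)
      warning(sprintf("assertion failed after '%s': cell (%d,%d) is %d, expected %d",
                      transform$name, a$i, a$j, actual, a$value),
              call. = FALSE)
  }
  out
}

#' Compose transformations into one edit script
#'
#' `apply_transformation(g, compose_transformations(t1, t2))` equals
#' applying `t1` then `t2`.
#'
#' @param ... `chd_transformation` objects, or a single list of them.
#' @return A composite `chd_transformation` with concatenated steps.
#' @export
compose_transformations <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && !inherits(ts[[1L]], "chd_transformation"))
    ts <- ts[[1L]]
  if (!length(ts)) stop("need at least one transformation to compose")
  stopifnot(all(vapply(ts, inherits, logical(1), "chd_transformation")))
  if (length(ts) == 1L) return(ts[[1L]])
  transformation(
    name = paste(vapply(ts, `[[`, character(1), "name"), collapse = " + "),
    category = "composite",
    steps = do.call(c, lapply(ts, `[[`, "steps")),
    parameters = do.call(c, lapply(ts, `[[`, "parameters")),
    asserts = do.call(c, lapply(ts, `[[`, "asserts")))
}

#' Look up any transformation by name
#'
#' Searches diseases, procedures, and the special composites
#' (`"extreme_TOF"`).
#'
#' @param name Catalog key.
#' @param parameters Passed to [get_disease()] where applicable.
#' @return A `chd_transformation`.
#' @export
get_transformation <- function(name, parameters = list()) {
  if (name %in% c("extreme_TOF", "extreme TOF")) return(extreme_tof())
  if (name %in% disease_names()) return(get_disease(name, parameters))
  if (name %in% procedure_names()) return(get_procedure(name))
  stop("unknown transformation '", name, "'; known: ",
       paste(c(disease_names(), procedure_names(), "extreme_TOF"),
             collapse = ", "))
}

#' Build a condition graph from the normal heart
#'
#' Convenience wrapper: starts from [build_normal_heart()] and applies the
#' named transformations in order.
#'
#' @param names Character vector of catalog keys (diseases, procedures, or
#'   `"extreme_TOF"`), applied left to right; `"normal"` alone returns the
#'   normal heart.
#' @param parameters Named list of parameter lists keyed by catalog key.
#' @param strict Passed to [apply_transformation()].
#' @return A `circulation_graph`.
#' @examples
#' tof_shunted <- build_condition(c("extreme_TOF", "right_mBT_shunt"))
#' @export
build_condition <- function(names, parameters = list(), strict = TRUE) {
  g <- build_normal_heart()
  for (nm in names[names != "normal"]) {
    p <- if (!is.null(parameters[[nm]])) parameters[[nm]] else list()
    g <- apply_transformation(g, get_transformation(nm, p), strict = strict)
  }
  g
}
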