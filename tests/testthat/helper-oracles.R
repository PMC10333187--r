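# Independent oracles and generators used across the suite.

# Reflexive transitive closure as an explicit Boolean power sum
# I + M + M^2 + ... + M^(n-1): deliberately a different algorithm from the
# package's reachability (igraph BFS / repeated squaring).
closure_power_sum <- function(m) {
  n <- nrow(m)
  acc <- diag(n)
  p <- diag(n)
  for (k in seq_len(n - 1L)) {
    p <- (p %*% m > 0) * 1
    acc <- acc + p
  }
  acc > 0
}

# Random hollow 0/1 matrix (simple digraph adjacency).
random_hollow_matrix <- function(n, p = 0.3) {
  m <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(m) <- 0L
  m
}

# Random circulation graph over generic vertices.
random_graph <- function(n, p = 0.3) {
  m <- random_hollow_matrix(n, p)
  vt <- vertex_table(abbr = paste0("V", seq_len(n)))
  from_binary_matrix(binary_adjacency(m, vt))
}

# Brute-force two-path viability on a plain matrix, via the power-sum
# closure (independent of the package's survival check).
viable_brute <- function(m, sources, lungs, target) {
  r <- closure_power_sum(m)
  for (L in lungs)
    if (any(r[sources, L]) && r[L, target]) return(TRUE)
  FALSE
}

normal_matrix <- function() to_binary_matrix(build_normal_heart())

# Bare integer entries of an adjacency matrix (drops class/vertex attrs).
entries <- function(m) {
  m <- unclass(m)
  attr(m, "vertices") <- NULL
  m
}

# Structural equality of two graphs: same vertex abbreviations in order,
# same edge set.
graphs_equal_helper <- function(a, b) {
  identical(a$vertices$abbr, b$vertices$abbr) &&
    identical(unclass(to_binary_matrix(a)), unclass(to_binary_matrix(b)))
}

# Temp file cleaned up when the calling test finishes.
withr_local_tempfile <- function(ext, env = parent.frame()) {
  f <- tempfile(fileext = ext)
  withr::defer(unlink(f), envir = env)
  f
}

# Package-internal scientific renderer, exposed for the formatting oracle.
count_graphs_render_helper <- function(k) {
  chdgraph:::scientific_3sf(chdgraph:::pow2_decimal(k))
}

expect_cells <- function(mat, cells) {
  # cells: list of c(i, j, expected)
  for (cc in cells) {
    expect_identical(
      unclass(mat)[cc[1L], cc[2L]], as.integer(cc[3L]),
      label = sprintf("cell (%d,%d)", cc[1L], cc[2L]))
  }
}
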