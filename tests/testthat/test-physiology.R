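test_that("reachable agrees with a Boolean transitive-closure oracle", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    m <- random_hollow_matrix(n, p = stats::runif(1, 0.1, 0.5))
    g <- from_binary_matrix(binary_adjacency(m, vertex_table(paste0("V", 1:n))))
    oracle <- closure_power_sum(m)
    i <- sample(n, 1); j <- sample(n, 1)
    expect_identical(reachable(g, i, j), unname(oracle[i, j]),
                     label = sprintf("rep %d: %d -> %d", rep, i, j))
  }
})

test_that("reachable handles trivial cases and bad indices", {
  g <- from_binary_matrix(binary_adjacency(matrix(0L, 3, 3),
                                           vertex_table(paste0("V", 1:3))))
  expect_true(reachable(g, 2, 2))   # empty path
  expect_false(reachable(g, 1, 2))  # no edges
  expect_error(reachable(g, 1, 9), "out of range")
})

test_that("survival rule reproduces the classic clinical cases", {
  expect_true(check_survival(build_normal_heart())$viable)
  # transposition without a shunt: venous return bypasses the lungs
  dtga <- build_condition("d-TGA")
  expect_false(check_survival(dtga)$viable)
  expect_false(reachable(dtga, 1, 8))  # SVC never reaches the right lung
  # a VSD restores both paths
  expect_true(check_survival(build_condition(c("d-TGA", "VSD")))$viable)
  # extreme TOF is lethal unpalliated, viable after a right mBT shunt
  expect_false(check_survival(build_condition("extreme_TOF"))$viable)
  expect_true(check_survival(
    build_condition(c("extreme_TOF", "right_mBT_shunt")))$viable)
})

test_that("viability reports carry valid witness paths for qualifying lungs", {
  rep_n <- check_survival(build_normal_heart())
  expect_setequal(rep_n$qualifying_lungs, c(8L, 9L))
  g <- build_normal_heart()
  for (w in rep_n$witness_paths) {
    vp <- w$venous_path; ap <- w$arterial_path
    expect_true(vp[1] %in% c(1L, 2L))
    expect_identical(ap[length(ap)], 16L)
    for (k in seq_len(length(vp) - 1))
      expect_true(has_edge(g, vp[k], vp[k + 1]))
    for (k in seq_len(length(ap) - 1))
      expect_true(has_edge(g, ap[k], ap[k + 1]))
  }
})

test_that("removing edges never turns a non-viable heart viable (monotonicity)", {
  set.seed(202)
  for (rep in 1:20) {
    g <- build_normal_heart()
    was_viable <- TRUE
    for (step in 1:10) {
      if (!n_edges(g)) break
      drop <- g$edges[sample(n_edges(g), 1), , drop = FALSE]
      g <- apply_transformation(g, transformation(
        "ablation", "composite",
        steps = list(edit_step("remove_edge", from = drop[1], to = drop[2]))))
      now_viable <- check_survival(g)$viable
      expect_false(!was_viable && now_viable)
      was_viable <- now_viable
    }
  }
  # isolating both lungs is always lethal
  g <- apply_transformation(build_normal_heart(), transformation(
    "no lungs", "composite",
    steps = list(edit_step("isolate_vertex", index = 8),
                 edit_step("isolate_vertex", index = 9))))
  expect_false(check_survival(g)$viable)
})

test_that("classify_diff of identical matrices is empty", {
  A <- normal_matrix()
  d <- classify_diff(A, A)
  expect_length(d$categories, 0)
  expect_identical(nrow(d$added_edges), 0L)
  expect_identical(nrow(d$removed_edges), 0L)
  expect_length(d$rewirings, 0)
})

test_that("classify_diff assigns each cataloged disease its structural category", {
  A <- normal_matrix()
  section <- list(
    PDA = "increased_vertices", MAPCA = "increased_vertices",
    PLSVC = "increased_vertices",
    absent_pulmonary_artery = "decreased_vertices",
    ASD = "increased_edges", VSD = "increased_edges",
    aortopulmonary_septal_defect = "increased_edges",
    tricuspid_atresia = "decreased_edges",
    pulmonary_atresia = "decreased_edges",
    anomalous_pulmonary_venous_return = "abnormal_connections",
    `d-TGA` = "abnormal_connections", `l-TGA` = "abnormal_connections",
    DORV = "abnormal_connections",
    truncus_arteriosus = "abnormal_connections")
  for (nm in names(section)) {
    d <- classify_diff(A, to_binary_matrix(build_condition(nm)))
    expect_true(section[[nm]] %in% d$categories,
                label = sprintf("%s in categories of %s", section[[nm]], nm))
  }
  # the pure-category cases trigger nothing else
  expect_identical(classify_diff(A, to_binary_matrix(build_condition("PDA")))$categories,
                   "increased_vertices")
  expect_identical(classify_diff(A, to_binary_matrix(build_condition("VSD")))$categories,
                   "increased_edges")
  expect_identical(classify_diff(A, to_binary_matrix(build_condition("d-TGA")))$categories,
                   "abnormal_connections")
})

test_that("classify_diff reports the transposition rewirings at both ventricles", {
  d <- classify_diff(normal_matrix(),
                     to_binary_matrix(build_condition("d-TGA")))
  expect_length(d$rewirings, 2)
  piv <- vapply(d$rewirings, function(r) r$vertex, integer(1))
  expect_setequal(piv, c(4L, 15L))
  rv <- d$rewirings[[which(piv == 4L)]]
  expect_identical(unname(rv$removed), c(4L, 5L))
  expect_identical(unname(rv$added), c(4L, 16L))
})

test_that("classify_diff details PDA and absent-PA structure", {
  A <- normal_matrix()
  d <- classify_diff(A, to_binary_matrix(build_condition("PDA")))
  expect_identical(d$added_vertices$abbr, "PDA")
  expect_identical(unname(d$added_edges), rbind(c(18L, 25L), c(25L, 5L)))
  d2 <- classify_diff(A, to_binary_matrix(apply_transformation(
    build_normal_heart(),
    get_disease("absent_pulmonary_artery", list(side = "right")))))
  expect_identical(d2$isolated_vertices, 6L)
  expect_identical(d2$categories, "decreased_vertices")
  # relabeling is reported but is not an edge category
  d3 <- classify_diff(A, to_binary_matrix(build_condition("truncus_arteriosus")))
  expect_identical(d3$relabeled_vertices, 16L)
})

test_that("classify_diff recovers the net edge changes of every catalog script", {
  A <- normal_matrix()
  for (nm in c(disease_names(), procedure_names())) {
    V <- to_binary_matrix(build_condition(nm))
    d <- classify_diff(A, V)
    n <- nrow(V)
    Ap <- matrix(0L, n, n); Ap[1:24, 1:24] <- unclass(A)
    dif <- unclass(V) - Ap
    expect_identical(nrow(d$added_edges), sum(dif == 1L), label = nm)
    expect_identical(nrow(d$removed_edges), sum(dif == -1L), label = nm)
    # rewirings reference only listed diff edges
    for (r in d$rewirings) {
      expect_identical(dif[r$removed[1], r$removed[2]], -1L)
      expect_identical(dif[r$added[1], r$added[2]], 1L)
    }
  }
  expect_error(classify_diff(to_binary_matrix(build_condition("PDA")), A),
               "more vertices")
})

test_that("the anomalous venous return detector implements the quantifier", {
  expect_false(has_anomalous_pulmonary_venous_return(normal_matrix()))
  apvr <- to_binary_matrix(build_condition("anomalous_pulmonary_venous_return"))
  expect_true(has_anomalous_pulmonary_venous_return(apvr))
  for (vein in c(10, 11, 12, 13)) {
    m <- to_binary_matrix(apply_transformation(
      build_normal_heart(),
      get_disease("anomalous_pulmonary_venous_return",
                  list(vein = vein, target = 1))))
    expect_true(has_anomalous_pulmonary_venous_return(m))
  }
})

test_that("diagnosis finds exact catalog matches at distance zero", {
  catalog <- build_condition_catalog()
  dx <- diagnose(normal_matrix(), catalog)
  expect_identical(dx$condition[1], "normal heart")
  expect_identical(dx$distance[1], 0L)

  dtga_vsd <- to_binary_matrix(build_condition(c("d-TGA", "VSD")))
  dx2 <- diagnose(dtga_vsd, catalog)
  expect_identical(dx2$condition[1], "d-TGA with VSD")
  expect_identical(dx2$distance[1], 0L)

  # a lone right-to-left atrial shunt edge
  M <- unclass(normal_matrix()); M[3, 14] <- 1L
  dx3 <- diagnose(binary_adjacency(M, circulation_vertices()), catalog)
  expect_match(dx3$condition[1], "^ASD")
  expect_identical(dx3$distance[1], 0L)
  expect_gte(dx3$distance[2], 1L)

  # every catalog member self-matches at distance zero
  for (nm in names(catalog)) {
    d <- vapply(catalog, hamming_distance, integer(1), b = catalog[[nm]])
    expect_identical(unname(d[nm]), 0L, label = nm)
  }
})

test_that("the diagnosis distance is a metric on equal-dimension matrices", {
  catalog <- build_condition_catalog()
  dims <- vapply(catalog, nrow, integer(1))
  mats <- catalog[dims == 24L][1:6]
  for (a in mats) for (b in mats) {
    expect_identical(hamming_distance(a, b), hamming_distance(b, a))
    for (cc in mats)
      expect_lte(hamming_distance(a, b),
                 hamming_distance(a, cc) + hamming_distance(cc, b))
  }
  expect_identical(hamming_distance(mats[[1]], mats[[1]]), 0L)
})
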