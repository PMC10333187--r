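# Catalog fidelity: applying each cataloged disease/procedure to the
# normal heart must reproduce every printed matrix element of its source
# row, exhaustively and table-driven.

fidelity_cases <- list(
  list(name = "PDA", build = "PDA", dim = 25L,
       cells = list(c(18, 25, 1), c(25, 5, 1))),
  list(name = "MAPCA right lung", trans = list("MAPCA", list(lung = "right")),
       dim = 25L, cells = list(c(18, 25, 1), c(25, 8, 1))),
  list(name = "MAPCA left lung", trans = list("MAPCA", list(lung = "left")),
       dim = 25L, cells = list(c(18, 25, 1), c(25, 9, 1))),
  list(name = "PLSVC", build = "PLSVC", dim = 25L,
       cells = list(c(25, 3, 1))),
  list(name = "absent right PA",
       trans = list("absent_pulmonary_artery", list(side = "right")),
       dim = 24L, cells = list(c(5, 6, 0), c(6, 8, 0))),
  list(name = "absent left PA",
       trans = list("absent_pulmonary_artery", list(side = "left")),
       dim = 24L, cells = list(c(5, 7, 0), c(7, 9, 0))),
  list(name = "ASD bidirectional", build = "ASD", dim = 24L,
       cells = list(c(3, 14, 1), c(14, 3, 1))),
  list(name = "VSD bidirectional", build = "VSD", dim = 24L,
       cells = list(c(4, 15, 1), c(15, 4, 1))),
  list(name = "aortopulmonary septal defect",
       build = "aortopulmonary_septal_defect", dim = 24L,
       cells = list(c(5, 16, 1), c(16, 5, 1))),
  list(name = "tricuspid atresia", build = "tricuspid_atresia", dim = 24L,
       cells = list(c(3, 4, 0))),
  list(name = "pulmonary atresia", build = "pulmonary_atresia", dim = 24L,
       cells = list(c(4, 5, 0))),
  list(name = "anomalous pulmonary venous return (default RUPV to RA)",
       build = "anomalous_pulmonary_venous_return", dim = 24L,
       cells = list(c(10, 14, 0), c(10, 3, 1))),
  list(name = "d-TGA", build = "d-TGA", dim = 24L,
       cells = list(c(4, 5, 0), c(4, 16, 1), c(15, 16, 0), c(15, 5, 1),
                    c(3, 4, 1), c(3, 15, 0), c(14, 15, 1), c(14, 4, 0))),
  list(name = "l-TGA", build = "l-TGA", dim = 24L,
       cells = list(c(3, 4, 0), c(3, 15, 1), c(14, 15, 0), c(14, 4, 1),
                    c(4, 5, 0), c(4, 16, 1), c(15, 16, 0), c(15, 5, 1))),
  list(name = "DORV", build = "DORV", dim = 24L,
       cells = list(c(4, 5, 1), c(4, 16, 1), c(15, 16, 0), c(15, 5, 0))),
  list(name = "truncus arteriosus", build = "truncus_arteriosus", dim = 24L,
       cells = list(c(4, 5, 0), c(4, 16, 1), c(15, 16, 1), c(15, 5, 0),
                    c(16, 5, 1))),
  list(name = "right mBT shunt", build = "right_mBT_shunt", dim = 25L,
       cells = list(c(23, 25, 1), c(25, 6, 1))),
  list(name = "left mBT shunt", build = "left_mBT_shunt", dim = 25L,
       cells = list(c(21, 25, 1), c(25, 7, 1))),
  list(name = "Norwood with right mBT shunt",
       build = "norwood_with_right_mBT", dim = 25L,
       cells = list(c(5, 6, 0), c(5, 7, 0), c(5, 16, 1),
                    c(23, 25, 1), c(25, 6, 1), c(6, 7, 1))),
  list(name = "bidirectional Glenn", build = "bidirectional_glenn",
       dim = 24L, cells = list(c(1, 3, 0), c(1, 6, 1))),
  list(name = "Fontan", build = "fontan", dim = 24L,
       cells = list(c(2, 3, 0), c(2, 6, 1))),
  list(name = "extreme TOF with right mBT shunt",
       build = c("extreme_TOF", "right_mBT_shunt"), dim = 25L,
       cells = list(c(23, 25, 1), c(25, 6, 1), c(4, 15, 1), c(15, 4, 1),
                    c(4, 5, 0), c(5, 6, 0), c(6, 5, 1)))
)

test_that("every printed catalog element is reproduced from the normal heart", {
  for (cs in fidelity_cases) {
    g <- if (!is.null(cs$build)) build_condition(cs$build)
         else apply_transformation(build_normal_heart(),
                                   get_disease(cs$trans[[1]], cs$trans[[2]]))
    m <- to_binary_matrix(g)
    expect_identical(nrow(m), cs$dim, label = paste(cs$name, "dimension"))
    expect_cells(m, cs$cells)
  }
})

test_that("the d-TGA script has the same matrix effect as the column interchange", {
  A <- normal_matrix()
  C <- to_binary_matrix(build_condition("d-TGA"))
  expect_identical(unclass(C), unclass(interchange_columns(A, 5, 16)))
  L <- to_binary_matrix(build_condition("l-TGA"))
  expect_identical(unclass(L),
                   unclass(interchange_columns(
                     interchange_columns(A, 4, 15), 5, 16)))
})

test_that("the arterial switch is the involution of transposition", {
  A <- normal_matrix()
  switched <- build_condition(c("d-TGA", "arterial_switch"))
  expect_identical(unclass(to_binary_matrix(switched)), unclass(A))
  twice <- build_condition(c("arterial_switch", "arterial_switch"))
  expect_identical(unclass(to_binary_matrix(twice)), unclass(A))
})

test_that("apply never mutates its input and labels the output", {
  nh <- build_normal_heart()
  before <- to_binary_matrix(nh)
  out <- apply_transformation(nh, get_disease("VSD"))
  expect_identical(unclass(to_binary_matrix(nh)), unclass(before))
  expect_match(out$label, "VSD")
})

test_that("strict mode rejects inapplicable steps; lenient mode warns and skips", {
  nh <- build_normal_heart()
  vsd <- get_disease("VSD")
  once <- apply_transformation(nh, vsd)
  expect_error(apply_transformation(once, vsd), "already present")
  w <- capture_warnings(again <- apply_transformation(once, vsd,
                                                      strict = FALSE))
  expect_length(w, 2)  # both shunt directions already present
  expect_match(w, "already present", all = TRUE)
  expect_identical(unclass(to_binary_matrix(again)),
                   unclass(to_binary_matrix(once)))
  expect_error(
    apply_transformation(build_condition("tricuspid_atresia"),
                         get_disease("tricuspid_atresia")),
    "not present")
})

test_that("the empty transformation is the identity edit", {
  nh <- build_normal_heart()
  idt <- transformation("identity", "composite", steps = list())
  expect_true(graphs_equal_helper(apply_transformation(nh, idt), nh))
})

test_that("compose concatenates scripts and equals sequential application", {
  nh <- build_normal_heart()
  glenn <- get_procedure("bidirectional_glenn")
  fontan <- get_procedure("fontan")
  seq_g <- apply_transformation(apply_transformation(nh, glenn), fontan)
  comp_g <- apply_transformation(nh, compose_transformations(glenn, fontan))
  expect_identical(unclass(to_binary_matrix(comp_g)),
                   unclass(to_binary_matrix(seq_g)))
  m <- to_binary_matrix(comp_g)
  expect_cells(m, list(c(1, 6, 1), c(2, 6, 1), c(1, 3, 0), c(2, 3, 0)))
  # singleton compose is the transformation itself
  expect_identical(compose_transformations(fontan), fontan)
  # compound disease: VSD + pulmonary atresia
  m2 <- to_binary_matrix(apply_transformation(
    nh, compose_transformations(get_disease("VSD"),
                                get_disease("pulmonary_atresia"))))
  expect_cells(m2, list(c(4, 5, 0), c(4, 15, 1)))
})

test_that("truncus arteriosus relabels vertex 16 without changing the dimension", {
  g <- build_condition("truncus_arteriosus")
  expect_identical(n_vertices(g), 24L)
  expect_identical(g$vertices$abbr[16], "TrA")
  expect_identical(g$vertices$name[16], "truncus arteriosus")
})

test_that("new vertices always take index n+1", {
  g <- build_condition("PDA")
  expect_identical(g$vertices$index[25], 25L)
  g2 <- apply_transformation(g, get_procedure("right_mBT_shunt"))
  expect_identical(g2$vertices$abbr[26], "mBT")
})

test_that("unknown names and invalid parameters produce informative errors", {
  expect_error(get_disease("nonsense"), "catalog holds")
  expect_error(get_procedure("nonsense"), "catalog holds")
  expect_error(get_disease("VSD", list(direction = "sideways")), "invalid value")
  expect_error(get_disease("VSD", list(bogus = 1)), "does not take")
  expect_error(get_disease("anomalous_pulmonary_venous_return",
                           list(target = 14)), "not allowed")
})

test_that("directional septal-defect variants add only the requested edge", {
  m <- to_binary_matrix(apply_transformation(
    build_normal_heart(), get_disease("ASD", list(direction = "right_to_left"))))
  expect_cells(m, list(c(3, 14, 1), c(14, 3, 0)))
  m2 <- to_binary_matrix(apply_transformation(
    build_normal_heart(), get_disease("VSD", list(direction = "left_to_right"))))
  expect_cells(m2, list(c(15, 4, 1), c(4, 15, 0)))
})

test_that("custom catalogs load from YAML in the shipped schema", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c(
    "diseases:",
    "  window_duct:",
    "    category: increased_edges",
    "    steps:",
    "      - {op: add_edge, from: 18, to: 5}",
    "procedures: {}"), tmp)
  cat2 <- load_catalog(tmp)
  expect_named(cat2$diseases, "window_duct")
  expect_identical(cat2$diseases$window_duct$category, "increased_edges")

  bad <- tempfile(fileext = ".yaml")
  writeLines("foo: 1", bad)
  expect_error(load_catalog(bad), "diseases")
})
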