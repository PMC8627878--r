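test_that("edge tables load with node-kind inference and validation", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\trole\tsign",
               "# a comment line",
               "A\tR1\tsubstrate\tunknown",
               "R1\tB\tproduct\tunknown",
               "B\tR1\tregulator\tinhibition"), tf)
  g <- load_edge_table(tf)
  expect_equal(nrow(g$substances), 2L)
  expect_equal(nrow(g$reactions), 1L)
  expect_equal(nrow(g$edges), 3L)
  expect_true(graph_equal(g, minimal_graph()))

  # appending a row that uses the reaction as a substrate source must fail
  writeLines(c("source\ttarget\trole\tsign",
               "A\tR1\tsubstrate\tunknown",
               "R1\tB\tproduct\tunknown",
               "B\tR1\tregulator\tinhibition",
               "R1\tR1\tsubstrate\tunknown"), tf)
  expect_error(load_edge_table(tf), "both substance and reaction.*R1")

  # missing role column is a format error
  writeLines(c("source\ttarget", "A\tR1"), tf)
  expect_error(load_edge_table(tf), "missing column")

  expect_error(load_edge_table(file.path(tempdir(), "nope.tsv")),
               "not found")
})

test_that("the trp fixture table round-trips through the edge dialect", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  g <- trp_fixture()
  write_edge_table(g, tf)
  g2 <- load_edge_table(tf)
  expect_equal(nrow(g2$substances), 13L)
  expect_equal(nrow(g2$reactions), 5L)
  expect_identical(sort(g2$substances$id), sort(g$substances$id))
  expect_equal(nrow(g2$edges), nrow(g$edges))
})

test_that("validate_graph reports all violations without raising", {
  expect_equal(nrow(validate_graph(minimal_graph())), 0L)
  expect_equal(nrow(validate_graph(typed_graph())), 0L)

  raw <- oscontour:::new_typed_graph(
    substances = data.frame(id = c("A", "B")),
    reactions = data.frame(id = "R1"),
    edges = data.frame(source = c("A", "A", "R1"),
                       target = c("R1", "R1", "A"),
                       role = c("substrate", "substrate", "substrate"),
                       sign = "unknown"))
  v <- validate_graph(raw)
  expect_true(any(v$rule == "edge_unique" & grepl("A R1", v$id)))
  expect_true(any(v$rule == "role_direction"))

  # product edge running substance -> reaction
  raw2 <- oscontour:::new_typed_graph(
    substances = data.frame(id = "A"),
    reactions = data.frame(id = "R1"),
    edges = data.frame(source = "A", target = "R1", role = "product",
                       sign = "unknown"))
  v2 <- validate_graph(raw2)
  expect_true(any(v2$rule == "role_direction" & grepl("product", v2$message)))

  # dangling endpoint and duplicate id
  raw3 <- oscontour:::new_typed_graph(
    substances = data.frame(id = c("A", "A")),
    reactions = data.frame(id = "R1"),
    edges = data.frame(source = "Z", target = "R1", role = "substrate",
                       sign = "unknown"))
  v3 <- validate_graph(raw3)
  expect_true(any(v3$rule == "node_id_unique"))
  expect_true(any(v3$rule == "edge_endpoint" & v3$id == "Z"))

  expect_error(typed_graph(
    substances = data.frame(id = "A"),
    reactions = data.frame(id = "A")), "duplicate node id")
})

test_that("GraphML writes and re-reads graphs identically", {
  tf <- withr::local_tempfile(fileext = ".graphml")

  write_graphml(typed_graph(), tf)
  e <- load_graphml(tf)
  expect_equal(nrow(e$substances) + nrow(e$reactions), 0L)

  g <- minimal_graph()
  write_graphml(g, tf)
  expect_true(graph_equal(load_graphml(tf), g))

  fx <- random_typed_graph(fixture_config(seed = 1))
  write_graphml(fx$graph, tf)
  expect_true(graph_equal(load_graphml(tf), fx$graph))
})

test_that("SBML import maps species, reactions and modifier signs", {
  tf <- withr::local_tempfile(fileext = ".sbml")
  write_min_sbml(tf)
  g <- load_sbml(tf)
  expect_equal(nrow(g$substances), 2L)
  expect_equal(nrow(g$reactions), 1L)
  expect_equal(nrow(g$edges), 3L)
  reg <- g$edges[g$edges$role == "regulator", ]
  expect_equal(reg$sign, "inhibition")
  expect_true(g$substances$is_boundary[g$substances$id == "B"])
  expect_equal(g$substances$name[g$substances$id == "A"], "substrate A")

  # unsigned modifier defaults to unknown
  write_min_sbml(tf, modifier_sbo = NULL)
  g2 <- load_sbml(tf)
  expect_equal(g2$edges$sign[g2$edges$role == "regulator"], "unknown")

  # activation SBO term
  write_min_sbml(tf, modifier_sbo = "SBO:0000459")
  g3 <- load_sbml(tf)
  expect_equal(g3$edges$sign[g3$edges$role == "regulator"], "activation")

  # not XML at all
  writeLines("this is not xml <", tf)
  expect_error(load_sbml(tf), "cannot parse")

  # zero reactions
  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level2/version4">',
               '<model id="empty"><listOfSpecies>',
               '<species id="A" compartment="c"/>',
               '</listOfSpecies></model></sbml>'), tf)
  expect_error(load_sbml(tf), "no reactions")
})

test_that("exported SBML recovers the contour-induced typed graph", {
  g <- trp_fixture()
  cn <- enumerate_contours(g)[[1]]
  model <- build_contour_model(cn, g)
  tf <- withr::local_tempfile(fileext = ".sbml")
  export_sbml(model, tf)
  back <- load_sbml(tf)
  expect_true(graph_equal(back, contour_subgraph(cn, g),
                          ignore_boundary = TRUE))
  # boundary flags follow the model's species split
  expect_setequal(back$substances$id[back$substances$is_boundary],
                  model$boundary$id)
  expect_equal(length(enumerate_contours(back)), 1L)
})
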