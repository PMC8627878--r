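test_that("fixture configs are validated", {
  expect_error(fixture_config(), "seed is mandatory")
  expect_error(fixture_config(planted_lengths = 1, seed = 1),
               "at least 2 substances")
  expect_error(fixture_config(n_substances = 3, n_reactions = 3,
                              n_planted_contours = 2, planted_lengths = 2,
                              seed = 1), "budget")
})

test_that("generation is deterministic per seed and always valid", {
  cfg <- fixture_config(n_substances = 9, n_reactions = 7,
                        edge_density = 2, n_planted_contours = 2,
                        planted_lengths = c(2, 3), seed = 42)
  a <- random_typed_graph(cfg)
  b <- random_typed_graph(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(
    serialize(random_typed_graph(fixture_config(seed = 7)), NULL),
    serialize(random_typed_graph(fixture_config(seed = 8)), NULL)))
  for (seed in c(0, 3, 11, 27)) {
    fx <- random_typed_graph(fixture_config(
      n_substances = 10, n_reactions = 8, edge_density = 2,
      n_planted_contours = 2, planted_lengths = c(2, 4), seed = seed))
    expect_equal(nrow(validate_graph(fx$graph)), 0L)
    found <- contour_ids(enumerate_contours(fx$graph))
    expect_true(all(contour_ids(fx$planted) %in% found))
    for (p in fx$planted) expect_true(validate_contour(p, fx$graph))
  }
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(runif(1))
  invisible(random_typed_graph(fixture_config(seed = 5)))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("the trp fixture encodes the printed pathway", {
  g <- trp_fixture()
  expect_equal(nrow(validate_graph(g)), 0L)
  expect_equal(nrow(g$substances), 13L)
  expect_equal(nrow(g$reactions), 5L)
  expect_setequal(
    g$substances$id,
    c("CHOR", "GLN", "PYR", "GLU", "AN", "PRPP", "NPRAN", "PPI",
      "CPAD5P", "IGP", "SER", "T3P1", "TRP"))
  # end-product inhibition of the entry reaction
  reg <- g$edges[g$edges$role == "regulator", ]
  expect_equal(nrow(reg), 1L)
  expect_identical(reg$source, "TRP")
  expect_identical(reg$sign, "inhibition")
  expect_length(enumerate_contours(g), 1L)
  expect_length(enumerate_contours(g)[[1]]$substances, 5L)
})

test_that("ring-repression networks produce both graph and dynamics", {
  rr <- ring_repression_network(3)
  expect_equal(nrow(validate_graph(rr$graph)), 0L)
  expect_equal(nrow(rr$graph$substances), 3L)
  expect_s3_class(rr$model, "ode_system")
  expect_error(ring_repression_network(2), "n_genes")
  expect_error(ring_repression_network(3, extra_links = list(c(1, 9))),
               "gene indices")
  # gene-network graphs have no mass-flow cycle, hence no contours
  expect_length(enumerate_contours(rr$graph), 0L)
})

test_that("the repressilator ring oscillates only at high cooperativity", {
  lab <- function(m, t_end = 200)
    detect_oscillation(integrate_model(m, t_end = t_end))$overall_label
  expect_equal(lab(ring_repression_network(3)$model), "sustained")
  expect_false(lab(ring_repression_network(3, h = 1)$model) == "sustained")
})

test_that("one added repressive link switches the 4-gene chain to cyclic", {
  lab <- function(m) detect_oscillation(
    integrate_model(m, t_end = 400))$overall_label
  base <- ring_repression_network(4, ring_closed = FALSE)
  expect_equal(lab(base$model), "steady")
  # closing an odd negative circuit with a single extra repression
  switched <- ring_repression_network(4, ring_closed = FALSE,
                                      extra_links = list(c(3, 1)))
  expect_equal(lab(switched$model), "sustained")
  expect_equal(nrow(switched$graph$edges) - nrow(base$graph$edges), 1L)
  # the closed symmetric double-repression network stays stationary
  dbl <- ring_repression_network(4, repressors_per_gene = 2)
  expect_equal(lab(dbl$model), "steady")
})
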