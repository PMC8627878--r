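test_that("graphs without inhibitory closure yield no contours", {
  g <- typed_graph(
    substances = data.frame(id = c("A", "B")),
    reactions = data.frame(id = c("R1", "R2")),
    edges = data.frame(
      source = c("A", "R1", "B", "R2"), target = c("R1", "B", "R2", "A"),
      role = c("substrate", "product", "substrate", "product"),
      sign = "unknown"))
  # pure mass-flow cycle, no regulator edge at all
  expect_length(enumerate_contours(g), 0L)
  expect_length(brute_force_contours(g), 0L)

  # activation-closed loop does not qualify either
  g2 <- typed_graph(
    substances = g$substances, reactions = g$reactions,
    edges = rbind(g$edges, data.frame(source = "B", target = "R1",
                                      role = "regulator",
                                      sign = "activation")))
  expect_length(enumerate_contours(g2), 0L)
})

test_that("a planted chain closed by end-product inhibition is found once", {
  fx <- random_typed_graph(fixture_config(
    n_substances = 5, n_reactions = 5, edge_density = 0,
    n_planted_contours = 1, planted_lengths = 5, seed = 0))
  found <- enumerate_contours(fx$graph)
  expect_length(found, 1L)
  expect_equal(found[[1]]$n_nodes, 10L)
  expect_identical(contour_ids(found), contour_ids(fx$planted))
  expect_identical(contour_ids(brute_force_contours(fx$graph)),
                   contour_ids(found))
})

test_that("the trp graph has exactly one contour, in pathway order", {
  g <- trp_fixture()
  found <- enumerate_contours(g)
  expect_length(found, 1L)
  expect_identical(found[[1]]$substances,
                   c("AN", "NPRAN", "CPAD5P", "IGP", "TRP"))
  expect_identical(found[[1]]$regulated_reaction, "AS")
  expect_equal(found[[1]]$n_nodes, 10L)
  rep <- contour_report(found, g)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$inhibitor, "L-tryptophan")
  # canonical id starts at the anthranilate-producing reaction
  expect_match(found[[1]]$canonical_id, "^AS\\|AN\\|")
})

test_that("canonicalization is representation-invariant and injective", {
  # same cycle assembled from different traversals has one id
  a <- contour(c("S1", "S2", "S3"), c("R2", "R3"), "R1")
  b <- contour(substances = c("S1", "S2", "S3"),
               reactions = c("R2", "R3"), regulated_reaction = "R1")
  expect_identical(a$canonical_id, b$canonical_id)
  # node-disjoint contours get distinct ids
  d <- contour(c("T1", "T2", "T3"), c("Q2", "Q3"), "Q1")
  expect_false(identical(a$canonical_id, d$canonical_id))
  # malformed contours are rejected
  expect_error(contour(c("S1", "S2"), character(), "R1"), "fewer reaction")
  expect_error(contour(c("S1", "S1"), "R2", "R1"), "repeats node")
  expect_error(contour("S1", character(), "R1"), "more than 3")
})

test_that("two contours sharing a substance are each reported once", {
  # two 2-substance loops sharing the inhibitor substance X:
  #   R1 -> A -> R2 -> X -| R1   and   Q1 -> B -> Q2 -> X -| Q1
  g <- typed_graph(
    substances = data.frame(id = c("A", "B", "X")),
    reactions = data.frame(id = c("R1", "R2", "Q1", "Q2")),
    edges = data.frame(
      source = c("R1", "A", "R2", "Q1", "B", "Q2", "X", "X"),
      target = c("A", "R2", "X", "B", "Q2", "X", "R1", "Q1"),
      role = c("product", "substrate", "product",
               "product", "substrate", "product", "regulator", "regulator"),
      sign = c(rep("unknown", 6), "inhibition", "inhibition")))
  found <- enumerate_contours(g)
  expect_length(found, 2L)
  expect_identical(contour_ids(brute_force_contours(g)),
                   contour_ids(found))
})

test_that("size bounds are enforced and filtering is monotone", {
  expect_error(enumerate_contours(minimal_graph(), min_nodes = 3),
               "more than 3")
  expect_error(brute_force_contours(minimal_graph(), min_nodes = 2),
               "more than 3")
  g <- chain_contour_graph(5)
  expect_length(enumerate_contours(g, min_nodes = 4, max_nodes = 8), 0L)
  expect_length(enumerate_contours(g, min_nodes = 4, max_nodes = 10), 1L)
  # widening the window never removes results
  narrow <- contour_ids(enumerate_contours(g, min_nodes = 6,
                                           max_nodes = 10))
  wide <- contour_ids(enumerate_contours(g, min_nodes = 4, max_nodes = 20))
  expect_true(all(narrow %in% wide))
})

test_that("unknown-sign closures require the explicit opt-in", {
  g <- chain_contour_graph(3)
  g$edges$sign[g$edges$role == "regulator"] <- "unknown"
  g <- typed_graph(g$substances, g$reactions, g$edges)
  expect_length(enumerate_contours(g), 0L)
  relaxed <- enumerate_contours(g, assume_unknown_inhibitory = TRUE)
  expect_length(relaxed, 1L)
  expect_identical(contour_ids(brute_force_contours(
    g, assume_unknown_inhibitory = TRUE)), contour_ids(relaxed))
})

test_that("targeted search equals the exhaustive oracle on random graphs", {
  # moderate-size adversarial sample here; the full 100-seed sweep runs in
  # the acceptance suite
  for (seed in 0:24) {
    cfg <- fixture_config(n_substances = 8, n_reactions = 8,
                          edge_density = 1.5,
                          n_planted_contours = seed %% 3,
                          planted_lengths = c(2, 3),
                          allow_background_inhibition = seed %% 4 == 0,
                          seed = seed)
    fx <- random_typed_graph(cfg)
    a <- contour_ids(enumerate_contours(fx$graph))
    b <- contour_ids(brute_force_contours(fx$graph))
    expect_identical(a, b, label = paste("seed", seed))
    expect_true(all(contour_ids(fx$planted) %in% a),
                label = paste("planted recall, seed", seed))
    for (cn in enumerate_contours(fx$graph)) {
      expect_true(validate_contour(cn, fx$graph))
      expect_gt(cn$n_nodes, 3L)
    }
  }
})

test_that("the brute-force oracle refuses oversized graphs", {
  big <- typed_graph(
    substances = data.frame(id = sprintf("S%d", 1:11)),
    reactions = data.frame(id = sprintf("R%d", 1:10)),
    edges = data.frame(source = sprintf("S%d", 1:10),
                       target = sprintf("R%d", 1:10),
                       role = "substrate", sign = "unknown"))
  expect_error(brute_force_contours(big), "20 nodes")
})

test_that("contour reports are tabular with one row per contour", {
  g <- trp_fixture()
  empty <- contour_report(list(), g)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("canonical_id", "n_nodes", "substances",
                        "regulated_reaction", "inhibitor"))
  one <- contour_report(enumerate_contours(g), g)
  expect_equal(nrow(one), 1L)
  expect_match(one$substances, "Anthranilate")
})
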