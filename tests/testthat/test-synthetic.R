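test_that("universe generation is deterministic and validated", {
  expect_equal(gen_universe(5), sprintf("G%06d", 1:5))
  expect_identical(gen_universe(10, seed = 3), gen_universe(10, seed = 3))
  expect_error(gen_universe(0), class = "netpharm_validation_error")
})

test_that("target-set generation realizes region counts exactly", {
  universe <- gen_universe(500)
  fx <- gen_target_sets(
    universe,
    sizes = c(d1 = 77, d2 = 77, d3 = 56, T2 = 200, MI = 90),
    overlaps = list("d1&d2&d3&MI" = 12, "d1&MI" = 7, "d2&MI" = 7, "d3&MI" = 5),
    nested = c(MI = "T2"),
    seed = 4
  )
  verify_fixture(fx)
  sizes <- vapply(fx$sets, length, integer(1))
  expect_equal(unname(sizes), c(77L, 77L, 56L, 200L, 90L))
  # nesting: every MI gene is a T2 gene
  expect_true(containment_report(fx$sets$MI, fx$sets$T2)$is_subset)
  # the venn over the drug union and diseases finds the planted intersection
  drug_union <- aggregate_sources(fx$sets[c("d1", "d2", "d3")], "drugs")
  v <- venn(list(drug_union, fx$sets$T2, fx$sets$MI))
  expect_equal(length(v$intersection), 31L)
  # all-drug core of 12 is the intersection of the three drug sets
  v3 <- venn(unname(fx$sets[c("d1", "d2", "d3")]))
  expect_equal(length(v3$intersection), 12L)
})

test_that("disjoint and nested specs behave; unsatisfiable specs are typed errors", {
  universe <- gen_universe(100)
  fx <- gen_target_sets(universe, sizes = c(a = 10, b = 10), seed = 1)
  expect_equal(length(intersect(fx$sets$a$members, fx$sets$b$members)), 0L)

  nested <- gen_target_sets(universe, sizes = c(inner = 5, outer = 20),
                            nested = c(inner = "outer"), seed = 2)
  expect_true(containment_report(nested$sets$inner, nested$sets$outer)$is_subset)

  expect_error(
    gen_target_sets(universe, sizes = c(a = 3), overlaps = list("a&zz" = 1)),
    class = "netpharm_validation_error")
  expect_error(
    gen_target_sets(universe, sizes = c(a = 3, b = 9),
                    overlaps = list("a&b" = 5)),
    class = "netpharm_unsatisfiable_error")
  expect_error(
    gen_target_sets(gen_universe(5), sizes = c(a = 4, b = 4)),
    class = "netpharm_unsatisfiable_error")
})

test_that("generated PPI graphs honour their recorded truth", {
  fx <- gen_ppi(n_background = 25, module_sizes = c(6, 5, 4), n_hubs = 3,
                background_p = 0.05, n_isolated = 4, isolated_mode = "low_conf",
                seed = 10)
  verify_fixture(fx)
  g <- fx$graph
  expect_equal(igraph::vcount(g), 15 + 3 + 25 + 4)
  # planted edges survive the 0.7 filter; isolates do not
  filt <- drop_isolated(filter_confidence(g, 0.7))
  for (mod in fx$truth$planted_modules) {
    sub <- igraph::induced_subgraph(filt, mod)
    expect_equal(igraph::ecount(sub), choose(length(mod), 2))
  }
  expect_false(any(fx$truth$isolated %in% igraph::V(filt)$name))
  # the background layer is acyclic among background nodes
  bg <- igraph::induced_subgraph(g, intersect(fx$truth$background,
                                              igraph::V(g)$name))
  expect_equal(igraph::ecount(bg),
               igraph::vcount(bg) - igraph::components(bg)$no)
  # determinism
  fx2 <- gen_ppi(25, c(6, 5, 4), 3, 0.05, n_isolated = 4,
                 isolated_mode = "low_conf", seed = 10)
  expect_true(igraph::identical_graphs(fx$graph, fx2$graph))
  # planting hubs needs enough cliques
  expect_error(gen_ppi(10, c(5, 4), n_hubs = 2, seed = 1),
               class = "netpharm_validation_error")
})

test_that("edgeless and unplanted generator calls degenerate cleanly", {
  fx <- gen_ppi(n_background = 10, background_p = 0, seed = 1)
  expect_equal(igraph::ecount(fx$graph), 0)
  expect_equal(igraph::vcount(fx$graph), 10)
})

test_that("library generation plants terms verbatim and validates inputs", {
  universe <- gen_universe(200)
  planted <- list(CORE = universe[1:7])
  fx <- gen_library(universe, n_terms = 10, term_size_range = c(5, 5),
                    planted = planted, seed = 3)
  verify_fixture(fx)
  expect_equal(fx$library$terms$CORE, sort(universe[1:7]))
  expect_true(all(lengths(fx$library$terms[paste0("T", sprintf("%03d", 1:10))]) == 5))
  expect_equal(fx$truth$enriched_terms, "CORE")
  expect_error(gen_library(universe, planted = list(X = "NOT_IN_UNIVERSE")),
               class = "netpharm_validation_error")
  # a planted term covering a 7-gene query ranks first by q
  res <- ora(universe[1:7], fx$library)
  expect_equal(res$term[res$rank == 1], "CORE")
})
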