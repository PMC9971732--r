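write_lines_tmp <- function(lines) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("edge TSV parsing handles both score dialects and headers", {
  p <- write_lines_tmp(c("AGT\tMMP9\t907"))
  g <- read_edge_tsv(p)
  expect_equal(igraph::E(g)$weight, 0.907)

  p2 <- write_lines_tmp(c("AGT\tMMP9\t0.907"))
  expect_equal(igraph::E(read_edge_tsv(p2))$weight, 0.907)

  p3 <- write_lines_tmp(c("node1\tnode2\tcombined_score", "AGT\tMMP9\t700"))
  g3 <- read_edge_tsv(p3)
  expect_equal(igraph::E(g3)$weight, 0.7)
})

test_that("duplicate and reversed rows collapse to one max-weight edge", {
  p <- write_lines_tmp(c("A\tB\t0.8", "B\tA\t0.9"))
  g <- read_edge_tsv(p)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 0.9)
})

test_that("malformed rows fail with a line number", {
  p <- write_lines_tmp(c("A\tB\t0.5", "A\tC\tnot_a_number"))
  expect_error(read_edge_tsv(p), "line 2", class = "netpharm_parse_error")
  p2 <- write_lines_tmp(c("A\tB\t0.5", "A"))
  expect_error(read_edge_tsv(p2), "line 2", class = "netpharm_parse_error")
})

test_that("confidence filtering is inclusive at the threshold and monotone", {
  p <- write_lines_tmp(c("A\tB\t0.69", "A\tC\t0.70", "B\tC\t0.95"))
  g <- read_edge_tsv(p)
  expect_equal(igraph::ecount(filter_confidence(g, 0.7)), 2)
  expect_equal(igraph::ecount(filter_confidence(g, 0)), 3)
  expect_equal(igraph::ecount(filter_confidence(g, 1)), 0)
  # monotone: raising the threshold never adds edges
  counts <- vapply(seq(0, 1, by = 0.05),
                   function(t) igraph::ecount(filter_confidence(g, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # node set preserved until drop_isolated
  expect_equal(igraph::vcount(filter_confidence(g, 1)), 3)
})

test_that("isolate removal drops exactly the degree-zero nodes, idempotently", {
  fx <- gen_ppi(n_background = 20, module_sizes = c(6, 5, 4),
                background_p = 0.05, n_isolated = 5, isolated_mode = "bare",
                seed = 9)
  g <- fx$graph
  expect_equal(igraph::vcount(g), 15 + 20 + 5)
  g1 <- drop_isolated(g)
  expect_false(any(fx$truth$isolated %in% igraph::V(g1)$name))
  expect_true(all(igraph::degree(g1) > 0))
  g2 <- drop_isolated(g1)
  expect_equal(igraph::vcount(g2), igraph::vcount(g1))

  empty <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty)$name <- c("A", "B", "C")
  expect_equal(igraph::vcount(drop_isolated(empty)), 0)
})

test_that("graph statistics are exact", {
  tri <- igraph::make_graph(~ A-B, B-C, C-A)
  expect_equal(graph_stats(tri), list(n_nodes = 3, n_edges = 3, n_components = 1))
  two <- igraph::make_graph(~ A-B, C-D)
  expect_equal(graph_stats(two)$n_components, 2)
  expect_equal(graph_stats(two)$n_nodes, 4)
})

test_that("edge TSV writing round-trips the graph exactly", {
  fx <- gen_ppi(n_background = 15, module_sizes = c(5, 4),
                background_p = 0.1, seed = 4)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "g.tsv")
  write_edge_tsv(fx$graph, p)
  g2 <- read_edge_tsv(p)
  gd <- drop_isolated(fx$graph)  # isolates are not representable in edge lists
  expect_setequal(igraph::V(g2)$name, igraph::V(gd)$name)
  expect_equal(igraph::ecount(g2), igraph::ecount(gd))
  el2 <- igraph::as_edgelist(g2)
  key2 <- paste(pmin(el2[, 1], el2[, 2]), pmax(el2[, 1], el2[, 2]))
  eld <- igraph::as_edgelist(gd)
  keyd <- paste(pmin(eld[, 1], eld[, 2]), pmax(eld[, 1], eld[, 2]))
  expect_setequal(key2, keyd)
  expect_equal(igraph::E(g2)$weight[order(key2)],
               igraph::E(gd)$weight[order(keyd)])
})
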