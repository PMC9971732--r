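test_that("degree, MNC and MCC match hand values on canonical graphs", {
  k3 <- adj_to_igraph(matrix(1L, 3, 3, dimnames = list(paste0("K", 1:3), paste0("K", 1:3))) -
                        diag(1L, 3))
  expect_equal(unname(centrality_degree(k3)), rep(2, 3))
  expect_equal(unname(mnc(k3)), rep(2L, 3))          # neighbors adjacent
  expect_equal(unname(mcc(k3)), rep(2, 3))           # (3-1)! once

  star <- igraph::make_graph(~ C-L1, C-L2, C-L3, C-L4)
  expect_equal(unname(centrality_degree(star)[c("C", "L1")]), c(4, 1))
  expect_equal(unname(mnc(star)["C"]), 1L)           # leaves form singletons

  path <- igraph::make_graph(~ A-B, B-C)
  expect_equal(unname(mcc(path)["B"]), 2)            # 1! + 1!

  k4 <- adj_to_igraph(matrix(1L, 4, 4, dimnames = list(paste0("K", 1:4), paste0("K", 1:4))) -
                        diag(1L, 4))
  expect_equal(unname(mcc(k4)), rep(6, 4))           # (4-1)!

  lone <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(lone)$name <- "X"
  expect_equal(unname(centrality_degree(lone)), 0)
  expect_equal(unname(mnc(lone)), 0L)
  expect_equal(unname(mcc(lone)), 0)
})

test_that("EPC limit cases are exact and the path expectation is recovered", {
  path <- igraph::make_graph(~ A-B, B-C)
  full <- epc(path, epc_params(replicates = 50, retention_p = 1, seed = 1))
  expect_equal(unname(full), c(3, 3, 3))
  none <- epc(path, epc_params(replicates = 50, retention_p = 0, seed = 1))
  expect_equal(unname(none), c(1, 1, 1))
  # exact E|comp(B)| at p = 0.5 from 2^2 enumeration is 2
  est <- epc(path, epc_params(replicates = 4000, retention_p = 0.5, seed = 7))
  oracle <- exact_epc(matrix(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L), 3, 3,
                             dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
                      0.5)
  expect_equal(unname(oracle$mean["B"]), 2)
  expect_lt(abs(est[["B"]] - 2), 3 * oracle$sd[["B"]] / sqrt(4000))
})

test_that("EPC is deterministic for a fixed seed and leaves the session RNG alone", {
  g <- adj_to_igraph(rand_adj(8, 0.4, seed = 3))
  set.seed(99)
  before <- .Random.seed
  e1 <- epc(g, epc_params(200, 0.5, 11))
  expect_identical(.Random.seed, before)
  e2 <- epc(g, epc_params(200, 0.5, 11))
  expect_identical(e1, e2)
})

test_that("centralities match brute-force oracles on random graphs", {
  for (s in 1:30) {
    n <- sample(4:11, 1)
    a <- rand_adj(n, runif(1, 0.2, 0.6), seed = 1000 + s)
    g <- adj_to_igraph(a)
    expect_equal(centrality_degree(g), stats::setNames(rowSums(a), rownames(a)))
    expect_equal(as.integer(mnc(g)), as.integer(brute_mnc(a)))
    expect_equal(mcc(g), brute_mcc(a))
  }
})

test_that("MCC dominates degree and MNC never exceeds degree", {
  for (s in 1:15) {
    a <- rand_adj(10, 0.35, seed = 2000 + s)
    g <- adj_to_igraph(a)
    deg <- centrality_degree(g)
    pos <- deg >= 1
    expect_true(all(mcc(g)[pos] >= deg[pos]))
    expect_true(all(mnc(g) <= deg))
  }
})

test_that("the clique-count cap rejects pathological graphs", {
  # the Moon-Moser graph K_{3,3,3,3,3} has 3^5 = 243 maximal cliques
  blocks <- rep(1:5, each = 3)
  a <- outer(blocks, blocks, "!=") * 1L
  dimnames(a) <- list(sprintf("V%02d", 1:15), sprintf("V%02d", 1:15))
  g <- adj_to_igraph(a)
  expect_error(mcc(g, max_cliques = 100), class = "netpharm_clique_cap_error")
  expect_silent(mcc(g, max_cliques = 1000))
})

test_that("consensus rule uses strict inequality over per-algorithm means", {
  c5 <- igraph::make_ring(5)
  igraph::V(c5)$name <- paste0("R", 1:5)
  hb <- consensus_hubs(c5, epc_params(200, 0.5, 3))
  expect_equal(length(hb$hubs), 0L)  # vertex-transitive: all values = mean

  # two disjoint triangles plus a pendant attached to one of them:
  # hand evaluation of the rule picks out no node on the pendant side tie
  g <- igraph::make_graph(~ A-B, B-C, C-A, D-E, E-F, F-D, A-P)
  hb2 <- consensus_hubs(g, epc_params(2000, 0.5, 5))
  tab <- hb2$table
  means <- attr(tab, "means")
  manual <- tab$node[tab$degree > means["degree"] & tab$mnc > means["mnc"] &
                       tab$mcc > means["mcc"] & tab$epc > means["epc"]]
  expect_setequal(hb2$hubs$members, manual)
  expect_error(consensus_hubs(igraph::make_empty_graph(0, directed = FALSE)),
               class = "netpharm_empty_graph_error")
})

test_that("consensus hubs are invariant to vertex order and stable in the EPC seed", {
  fx <- gen_ppi(20, c(6, 6, 6), n_hubs = 3, background_p = 0.05, seed = 77)
  g <- drop_isolated(filter_confidence(fx$graph, 0.7))
  perm <- igraph::permute(g, sample(igraph::vcount(g)))
  h1 <- consensus_hubs(g, epc_params(500, 0.5, 1))
  h2 <- consensus_hubs(perm, epc_params(500, 0.5, 1))
  h3 <- consensus_hubs(g, epc_params(500, 0.5, 2))
  expect_setequal(h1$hubs$members, h2$hubs$members)
  expect_setequal(h1$hubs$members, h3$hubs$members)
})
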