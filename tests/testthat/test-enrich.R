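toy_library <- function() {
  universe <- sprintf("G%03d", 1:100)
  gene_set_library("toy", list(
    TERM_FULL = universe[1:10],     # will fully contain the query
    TERM_HALF = universe[6:15],
    TERM_MISS = universe[90:100]
  ), universe = universe)
}

test_that("hypergeometric p, odds ratio and ranks follow the contingency table", {
  lib <- toy_library()
  query <- sprintf("G%03d", 1:10)
  rows <- ora(query, lib)
  full <- rows[rows$term == "TERM_FULL", ]
  # N=100, n=10, K=10, k=10 -> p = 1 / C(100, 10)
  expect_equal(full$p, 1 / choose(100, 10))
  expect_equal(full$k, 10)
  expect_true(is.infinite(full$odds_ratio))

  half <- rows[rows$term == "TERM_HALF", ]
  expect_equal(half$k, 5)
  expect_equal(half$odds_ratio, (5 * 85) / (5 * 5))  # = 17

  miss <- rows[rows$term == "TERM_MISS", ]
  expect_equal(miss$k, 0)
  expect_equal(miss$p, 1)
  expect_equal(miss$odds_ratio, 0)
  expect_equal(rows$term[rows$rank == 1], "TERM_FULL")
})

test_that("ora matches the direct-summation oracle on random configurations", {
  set.seed(31)
  for (trial in 1:40) {
    N <- sample(10:60, 1)
    universe <- sprintf("U%03d", 1:N)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    term <- sample(universe, K)
    query <- sample(universe, n)
    lib <- gene_set_library("one", list(TT = term), universe = universe)
    row <- ora(query, lib)
    k <- length(intersect(term, query))
    expect_equal(row$p, hyper_tail_sum(k, K, n, N), tolerance = 1e-12)
    expect_equal(row$k, k)
  }
  # exhaustive subset-counting oracle at tiny N
  for (trial in 1:10) {
    N <- sample(6:9, 1)
    universe <- sprintf("U%03d", 1:N)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    term <- universe[1:K]
    query <- sample(universe, n)
    lib <- gene_set_library("one", list(TT = term), universe = universe)
    k <- length(intersect(term, query))
    expect_equal(ora(query, lib)$p, hyper_tail_exhaustive(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(rep(0.04, 6)), rep(0.04 * 6 / 6, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "netpharm_validation_error")
  set.seed(8)
  for (trial in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q <= 1))
    # monotone in ranked order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("odds ratio is invariant under simultaneous table transposition", {
  # swapping rows and columns of the 2x2 table maps (k,K,n,N) to (k,n,K,N)
  set.seed(12)
  for (trial in 1:20) {
    N <- sample(20:60, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    k <- sample(max(0, n + K - N):min(K, n), 1)
    or1 <- netpharm:::odds_ratio_2x2(k, K, n, N)
    or2 <- netpharm:::odds_ratio_2x2(k, n, K, N)
    expect_equal(or1, or2)
  }
})

test_that("top-term selection is deterministic under ties", {
  rows <- data.frame(
    term = c("B", "A", "C", "D", "E"),
    p = c(0.01, 0.01, 0.02, 0.5, 0.9),
    q = c(0.05, 0.05, 0.05, 0.6, 0.9),
    odds_ratio = c(3, 9, 6, 1, 0.5)
  )
  by_q <- top_terms(rows, by = "q", k = 3)
  expect_equal(by_q$term, c("A", "B", "C"))  # tie on q,p broken by name
  by_or <- top_terms(rows, by = "odds_ratio", k = 3)
  expect_equal(by_or$term, c("A", "C", "B"))
  expect_equal(nrow(top_terms(rows, by = "q", k = 99)), 5)
})

test_that("permutation NES separates covering regulons from misses", {
  universe <- sprintf("G%03d", 1:150)
  query <- universe[1:7]
  lib <- gene_set_library("tf", list(
    COVERS = universe[1:7],
    PARTIAL = universe[c(1, 2, 50:55)],
    MISSES = universe[100:120]
  ), universe = universe)
  res <- tf_nes(query, lib, n_perm = 500, seed = 42)
  expect_equal(res$tf[res$rank == 1], "COVERS")
  expect_equal(res$n_targets_hit[res$tf == "COVERS"], 7L)
  expect_gt(res$nes[res$tf == "COVERS"], 0)
  expect_lte(res$nes[res$tf == "MISSES"], 0)
  # deterministic under a fixed seed
  res2 <- tf_nes(query, lib, n_perm = 500, seed = 42)
  expect_identical(res, res2)
  expect_error(tf_nes(sprintf("X%03d", 1:200), lib, n_perm = 100, seed = 1),
               class = "netpharm_universe_error")
  expect_error(tf_nes(query, lib, n_perm = 50, seed = 1),
               class = "netpharm_validation_error")
})

test_that("GMT files round-trip through reader and writer", {
  dir <- withr::local_tempdir()
  lib <- toy_library()
  p <- file.path(dir, "lib.gmt")
  write_gmt(lib, p)
  lib2 <- read_gmt(p, name = "toy")
  expect_equal(lib2$terms, lib$terms)
  # default universe is the union of term genes, not the original background
  expect_equal(lib2$universe, sort(unique(unlist(lib$terms))))
  writeLines("BAD\tonly_two_fields", file.path(dir, "bad.gmt"))
  expect_error(read_gmt(file.path(dir, "bad.gmt")),
               class = "netpharm_parse_error")
})

test_that("empty effective queries are rejected", {
  lib <- toy_library()
  expect_error(ora(c("NOPE1", "NOPE2"), lib),
               class = "netpharm_empty_query_error")
})
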