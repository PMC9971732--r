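test_that("symbol normalization collapses case, whitespace and duplicates", {
  gs <- normalize_symbols(c("agt", "AGT ", "Agt"))
  expect_equal(gs$members, "AGT")
  expect_equal(length(gs), 1L)

  gs2 <- normalize_symbols(c("mmp9", "timp1"))
  expect_equal(gs2$members, c("MMP9", "TIMP1"))

  expect_equal(normalize_symbols(character())$members, character())
  expect_error(normalize_symbols(c("AGT", "  ")),
               class = "netpharm_validation_error")
})

test_that("alias mapping rewrites known tokens and flags unmapped ones", {
  amap <- c(P01019 = "AGT")
  gs <- normalize_symbols(c("P01019"), alias_map = amap)
  expect_equal(gs$members, "AGT")
  expect_equal(attr(gs, "unmapped"), character())

  gs2 <- normalize_symbols(c("p01019", "novel1"), alias_map = amap)
  expect_setequal(gs2$members, c("AGT", "NOVEL1"))
  expect_equal(attr(gs2, "unmapped"), "NOVEL1")
})

test_that("source aggregation unions members and accumulates provenance", {
  a <- gene_set("A", c("X", "Y"))
  b <- gene_set("B", c("Y", "Z"))
  agg <- aggregate_sources(list(A = a, B = b), "drug")
  expect_setequal(agg$members, c("X", "Y", "Z"))
  expect_setequal(agg$provenance[["Y"]], c("A", "B"))
  expect_equal(agg$provenance[["X"]], "A")

  single <- aggregate_sources(list(A = a), "drug")
  expect_equal(single$members, a$members)

  expect_error(aggregate_sources(stats::setNames(list(a, b), c("A", "A")), "x"),
               class = "netpharm_validation_error")
})

test_that("aggregation is idempotent and order-independent", {
  a <- gene_set("A", c("X", "Y"))
  b <- gene_set("B", c("Y", "Z"))
  ab <- aggregate_sources(list(A = a, B = b), "d")
  ba <- aggregate_sources(list(B = b, A = a), "d")
  expect_equal(ab$members, ba$members)
  expect_equal(ab$provenance, ba$provenance)
  again <- aggregate_sources(list(A = a, B = b, A2 = a), "d")
  expect_equal(again$members, ab$members)
})

test_that("venn regions are disjoint, exhaustive, and match brute force", {
  v <- venn(list(gene_set("A", c("X", "Y")), gene_set("B", c("Y", "Z"))))
  expect_equal(as.integer(v$region_counts[c("A", "B", "A&B")]), c(1L, 1L, 1L))
  expect_equal(v$intersection$members, "Y")

  same <- gene_set("A", c("P", "Q"))
  v2 <- venn(list(same, gene_set("B", c("P", "Q"))))
  expect_equal(v2$intersection$members, same$members)

  expect_error(venn(list(same)), class = "netpharm_validation_error")
  expect_error(venn(rep(list(gene_set("s", "X")), 7)),
               class = "netpharm_validation_error")

  # exhaustive property check on a 6-gene universe with 3 random sets:
  # every region's genes carry exactly that membership signature, regions
  # are pairwise disjoint, and counts sum to the union size
  universe <- paste0("G", 1:6)
  set.seed(42)
  for (trial in 1:25) {
    sets <- lapply(c("S1", "S2", "S3"), function(lb) {
      gene_set(lb, sample(universe, sample(1:6, 1)))
    })
    v3 <- venn(sets)
    expect_equal(sum(v3$region_counts),
                 length(unique(unlist(lapply(sets, `[[`, "members")))))
    all_genes <- unlist(v3$regions, use.names = FALSE)
    expect_equal(anyDuplicated(all_genes), 0L)
    for (key in names(v3$regions)) {
      labs <- strsplit(key, "&", fixed = TRUE)[[1]]
      for (g in v3$regions[[key]]) {
        membership <- vapply(sets, function(s) g %in% s$members, logical(1))
        expect_setequal(vapply(sets, `[[`, "", "label")[membership], labs)
      }
    }
  }
})

test_that("combine_related is commutative and obeys the size law", {
  a <- gene_set("a", c("X", "Y"))
  b <- gene_set("b", c("Y"))
  expect_setequal(combine_related(a, b)$members, c("X", "Y"))
  expect_equal(combine_related(a, gene_set("e"))$members, a$members)
  set.seed(7)
  pool <- sprintf("G%03d", 1:50)
  for (trial in 1:20) {
    s1 <- gene_set("s1", sample(pool, sample(1:30, 1)))
    s2 <- gene_set("s2", sample(pool, sample(1:30, 1)))
    u12 <- combine_related(s1, s2)
    u21 <- combine_related(s2, s1)
    expect_equal(u12$members, u21$members)
    expect_equal(length(u12),
                 length(s1) + length(s2) -
                   length(intersect(s1$members, s2$members)))
  }
})

test_that("containment reports subset status and missing genes", {
  expect_true(containment_report(gene_set("i", "X"), gene_set("o", c("X", "Y")))$is_subset)
  rep2 <- containment_report(gene_set("i", c("X", "Z")), gene_set("o", c("X", "Y")))
  expect_false(rep2$is_subset)
  expect_equal(rep2$missing$members, "Z")
})

test_that("gene list and alias files round-trip through readers", {
  dir <- withr::local_tempdir()
  gl <- file.path(dir, "genes.txt")
  writeLines(c("# comment", "agt", "MMP9", "", "agt"), gl)
  gs <- read_gene_list(gl)
  expect_equal(gs$members, c("AGT", "MMP9"))

  am <- file.path(dir, "alias.tsv")
  writeLines("P01019\tAGT", am)
  map <- read_alias_map(am)
  expect_equal(unname(map["P01019"]), "AGT")

  out <- file.path(dir, "out.txt")
  write_gene_list(gs, out)
  expect_equal(read_gene_list(out)$members, gs$members)
})
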