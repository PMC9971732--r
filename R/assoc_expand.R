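# Functional-association expansion: given a weighted association network and
# a seed gene set, rank non-seed genes by a degree-normalized connectivity
# score and return the top k.  This is a deterministic, local stand-in for
# web-service association tools: only direct seed adjacency contributes.

#' Read a functional-association network (geneA, geneB, weight)
#'
#' Three-column TSV with positive association strengths (not restricted to
#' \[0, 1\]). Duplicate/reversed pairs collapse keeping the maximum weight.
#'
#' @param path Input TSV; a header is detected automatically.
#' @return An undirected igraph with edge attribute `weight` (> 0).
#' @export
read_association_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (is.character(df[[3L]]) || is.na(suppressWarnings(as.numeric(df[1L, 3L])))) {
    df <- df[-1L, , drop = FALSE]  # header row
  }
  df[[3L]] <- as.numeric(df[[3L]])
  if (any(is.na(df[[3L]])) || any(df[[3L]] <= 0)) {
    np_stop("association weights must be positive numbers",
            "netpharm_parse_error")
  }
  df[[1L]] <- toupper(trimws(df[[1L]]))
  df[[2L]] <- toupper(trimws(df[[2L]]))
  as_weighted_graph(df)
}

#' Expand a seed set with its most associated network neighbors
#'
#' Scores every non-seed gene `g` adjacent to the seed set as
#' `score(g) = sum over seed neighbors s of w(g, s) / sqrt(deg(g))`,
#' where `deg(g)` is `g`'s full degree in the association network. The
#' square-root degree normalization discounts promiscuous genes that touch
#' everything. Candidates are ranked by descending score with lexicographic
#' tie-breaking, and the top `k` positive-score genes are returned.
#'
#' @param net Weighted association network (igraph, weights > 0).
#' @param seeds [gene_set] of seed genes; at least one must be present in
#'   the network.
#' @param k Maximum number of genes to return (default 20).
#' @param label Label of the returned set.
#' @return A [gene_set] of at most `k` genes, disjoint from the seeds, with
#'   attribute `"scores"` (named numeric, ranked). Genes with zero score are
#'   never returned even if fewer than `k` candidates score positively.
#' @export
expand_related <- function(net, seeds, k = 20L, label = "associated") {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    np_validation_error("'k' must be a positive integer")
  }
  k <- as.integer(k)
  nodes <- igraph::V(net)$name
  seed_in <- intersect(seeds$members, nodes)
  if (!length(seed_in)) {
    np_stop("none of the seed genes is present in the association network",
            "netpharm_seed_error")
  }
  el <- igraph::as_edgelist(net)
  w <- igraph::E(net)$weight
  # seed-incident edge weight accumulated on the non-seed endpoint
  is_seed_a <- el[, 1L] %in% seed_in
  is_seed_b <- el[, 2L] %in% seed_in
  cand_scores <- numeric(0)
  sel1 <- is_seed_a & !is_seed_b
  sel2 <- is_seed_b & !is_seed_a
  genes <- c(el[sel1, 2L], el[sel2, 1L])
  wts <- c(w[sel1], w[sel2])
  if (length(genes)) {
    raw <- tapply(wts, genes, sum)
    deg <- igraph::degree(net, v = names(raw))
    sc <- as.numeric(raw) / sqrt(as.numeric(deg))
    names(sc) <- names(raw)
    sc <- sc[sc > 0]
    ord <- order(-sc, names(sc))
    sc <- sc[ord]
    cand_scores <- utils::head(sc, k)
  }
  out <- gene_set(label, names(cand_scores),
                  lapply(stats::setNames(nm = names(cand_scores)),
                         function(m) "association_network"))
  attr(out, "scores") <- cand_scores
  out
}
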