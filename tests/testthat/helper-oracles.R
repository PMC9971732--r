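# Brute-force oracles, independent of the package's implementation paths:
# subset enumeration for cliques and neighborhood components, 2^m edge
# enumeration for percolation expectations, direct-summation and exhaustive
# subset-counting hypergeometric tails.  All operate on plain adjacency
# matrices or integers, never on igraph internals.

# random simple graph as a named adjacency matrix (n <= ~12 for oracles)
rand_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (runif(1) < p) a[i, j] <- a[j, i] <- 1L
    }
  }
  dimnames(a) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  a
}

adj_to_igraph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# all maximal cliques of size >= 2 by bitmask subset enumeration
brute_max_cliques <- function(a) {
  n <- nrow(a)
  subsets <- lapply(seq_len(2^n - 1L), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
  })
  is_clique <- vapply(subsets, function(s) {
    sum(a[s, s]) == length(s) * (length(s) - 1L)
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(cliques, function(s) {
    outside <- setdiff(seq_len(n), s)
    !any(vapply(outside, function(v) all(a[v, s] == 1L), logical(1)))
  }, logical(1))
  keep <- cliques[maximal]
  keep[lengths(keep) >= 2L]
}

brute_mcc <- function(a) {
  out <- stats::setNames(numeric(nrow(a)), rownames(a))
  for (cl in brute_max_cliques(a)) {
    out[cl] <- out[cl] + factorial(length(cl) - 1L)
  }
  out
}

# connected components of an induced vertex subset, by BFS on the matrix
adj_components <- function(a, vs) {
  unseen <- vs
  comps <- list()
  while (length(unseen)) {
    queue <- unseen[1L]
    comp <- integer()
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- intersect(which(a[v, ] == 1L), vs)
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1L]] <- comp
    unseen <- setdiff(unseen, comp)
  }
  comps
}

brute_mnc <- function(a) {
  out <- stats::setNames(integer(nrow(a)), rownames(a))
  for (v in seq_len(nrow(a))) {
    nb <- which(a[v, ] == 1L)
    if (!length(nb)) next
    out[v] <- max(lengths(adj_components(a, nb)))
  }
  out
}

# exact EPC by 2^m edge-subset enumeration: per-node expected component size
# and its standard deviation under independent edge retention
exact_epc <- function(a, p) {
  g <- adj_to_igraph(a)
  n <- nrow(a)
  m <- igraph::ecount(g)
  ex <- stats::setNames(numeric(n), rownames(a))
  ex2 <- numeric(n)
  for (mask in 0:(2^m - 1L)) {
    keep <- if (m > 0L) which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L) else integer()
    sub <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
    comp <- igraph::components(sub)
    sizes <- comp$csize[comp$membership]
    prob <- p^length(keep) * (1 - p)^(m - length(keep))
    ex <- ex + prob * sizes
    ex2 <- ex2 + prob * sizes^2
  }
  list(mean = ex, sd = sqrt(pmax(ex2 - ex^2, 0)))
}

# one-sided hypergeometric tail by direct summation of binomial coefficients
hyper_tail_sum <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# fully exhaustive tail: count n-subsets of 1..N overlapping 1..K in >= k
hyper_tail_exhaustive <- function(k, K, n, N) {
  if (k <= 0) return(1)
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  sum(hits >= k) / ncol(subsets)
}

# step-up BH by the textbook definition, in input order
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  pmin(q_sorted, 1)[order(ord)]
}
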