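# The four hub-screening centralities (degree, MNC, MCC, EPC) and the
# consensus rule: a node is a core target iff its value exceeds the
# per-algorithm mean on all four simultaneously.  Edge weights are ignored:
# the centralities operate on the filtered network's topology, as the
# Cytoscape plugin does.

#' Degree centrality
#'
#' @param g igraph object.
#' @return Named integer vector of neighbor counts.
#' @export
centrality_degree <- function(g) {
  igraph::degree(g, loops = FALSE)
}

#' Maximum neighborhood component (MNC)
#'
#' `MNC(v)` is the size of the largest connected component of the subgraph
#' induced by the open neighborhood `N(v)` (v excluded); 0 for isolated
#' nodes.
#'
#' @param g igraph object.
#' @return Named integer vector.
#' @export
mnc <- function(g) {
  n <- igraph::vcount(g)
  out <- stats::setNames(integer(n), igraph::V(g)$name)
  if (n == 0L) return(out)
  adj <- igraph::as_adj_list(g, mode = "all", loops = "ignore", multiple = FALSE)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) == 0L) next
    sub <- igraph::induced_subgraph(g, nb)
    out[[i]] <- max(igraph::components(sub)$csize)
  }
  out
}

#' Maximal clique centrality (MCC)
#'
#' `MCC(v)` sums `(|C| - 1)!` over every maximal clique `C` containing `v`.
#' Isolated nodes (no maximal clique of size >= 2) score 0. Cliques are
#' enumerated with igraph's Bron-Kerbosch implementation; a configurable cap
#' aborts on pathological graphs. Values are exact for maximal cliques of up
#' to 19 vertices (18! is below the double-precision integer limit); a
#' larger clique triggers a warning.
#'
#' @param g igraph object.
#' @param max_cliques Abort with an error when the graph has more maximal
#'   cliques than this (default 1e6).
#' @return Named numeric vector of non-negative integers.
#' @export
mcc <- function(g, max_cliques = 1e6) {
  out <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  if (igraph::vcount(g) == 0L) return(out)
  n_cl <- igraph::count_max_cliques(g, min = 2L)
  if (n_cl > max_cliques) {
    np_stop(sprintf("graph has %d maximal cliques, exceeding the cap of %g",
                    n_cl, max_cliques), "netpharm_clique_cap_error")
  }
  cl <- igraph::max_cliques(g, min = 2L)
  sizes <- lengths(cl)
  if (length(sizes) && max(sizes) > 19L) {
    warning("maximal clique larger than 19 vertices: MCC loses integer exactness")
  }
  contrib <- factorial(sizes - 1L)
  for (j in seq_along(cl)) {
    idx <- as.integer(cl[[j]])
    out[idx] <- out[idx] + contrib[[j]]
  }
  out
}

#' EPC Monte-Carlo parameters
#'
#' @param replicates Number of percolated replicate graphs (default 1000).
#' @param retention_p Independent edge-retention probability (default 0.5).
#' @param seed RNG seed making the estimate reproducible (default 1).
#' @return An `epc_params` list.
#' @export
epc_params <- function(replicates = 1000L, retention_p = 0.5, seed = 1L) {
  assert_scalar_number(replicates, "replicates", 1, Inf)
  assert_scalar_number(retention_p, "retention_p", 0, 1)
  assert_scalar_number(seed, "seed")
  structure(list(replicates = as.integer(replicates),
                 retention_p = retention_p, seed = as.integer(seed)),
            class = "epc_params")
}

# union-find with path halving over integer node ids
uf_components_sizes <- function(n, from, to) {
  from <- as.integer(from)
  to <- as.integer(to)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- tabulate(roots, nbins = n)
  sizes[roots]
}

#' Edge percolated component (EPC)
#'
#' `EPC(v)` estimates the expected size of `v`'s connected component
#' (counting `v` itself) when every edge is kept independently with
#' probability `retention_p`, averaged over `replicates` seeded Monte-Carlo
#' percolations. With `retention_p = 1` the value equals the component size
#' exactly; with 0 it is 1.
#'
#' @param g igraph object.
#' @param params An [epc_params()] object.
#' @return Named numeric vector.
#' @export
epc <- function(g, params = epc_params()) {
  if (!inherits(params, "epc_params")) params <- do.call(epc_params, params)
  n <- igraph::vcount(g)
  out <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (n == 0L) return(out)
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  if (m == 0L) return(out + 1)
  acc <- numeric(n)
  with_seed(params$seed, {
    for (r in seq_len(params$replicates)) {
      keep <- stats::runif(m) <= params$retention_p
      acc <- acc + uf_components_sizes(n, el[keep, 1L], el[keep, 2L])
    }
  })
  out[] <- acc / params$replicates
  out
}

#' Centrality table for the four hub-screening algorithms
#'
#' Computes degree, MNC, MCC and EPC for every node of `g`, the arithmetic
#' mean of each column over all nodes of the analyzed graph, and per-node
#' pass flags (`value > mean`, strictly).
#'
#' @param g igraph object (typically the confidence-filtered PPI network
#'   with isolated nodes removed).
#' @param epc_params Parameters forwarded to [epc()].
#' @return A data frame of class `centrality_table` with columns `node`,
#'   `degree`, `mnc`, `mcc`, `epc`, the four `pass_*` flags and `is_hub`;
#'   the per-algorithm means are stored in attribute `"means"`.
#' @export
centrality_table <- function(g, epc_params = netpharm::epc_params()) {
  if (igraph::vcount(g) == 0L) {
    np_stop("cannot analyze an empty graph", "netpharm_empty_graph_error")
  }
  tab <- data.frame(
    node = igraph::V(g)$name,
    degree = as.numeric(centrality_degree(g)),
    mnc = as.numeric(mnc(g)),
    mcc = as.numeric(mcc(g)),
    epc = as.numeric(epc(g, epc_params)),
    stringsAsFactors = FALSE
  )
  means <- vapply(tab[c("degree", "mnc", "mcc", "epc")], mean, numeric(1))
  for (a in names(means)) tab[[paste0("pass_", a)]] <- tab[[a]] > means[[a]]
  tab$is_hub <- tab$pass_degree & tab$pass_mnc & tab$pass_mcc & tab$pass_epc
  tab <- tab[order(tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "means") <- means
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' Consensus hub (core-target) selection
#'
#' A node is a core target iff its degree, MNC, MCC and EPC are all strictly
#' greater than the respective per-algorithm means over all nodes of the
#' analyzed graph. Ties at the mean fail; on a vertex-transitive graph every
#' value equals its mean and the hub set is empty.
#'
#' @inheritParams centrality_table
#' @param label Label for the returned hub [gene_set].
#' @return A `hub_result` list: `hubs` (a [gene_set]), `table` (the
#'   [centrality_table()]) and `means`.
#' @export
consensus_hubs <- function(g, epc_params = netpharm::epc_params(),
                           label = "core_targets") {
  tab <- centrality_table(g, epc_params)
  hubs <- tab$node[tab$is_hub]
  structure(list(
    hubs = gene_set(label, hubs,
                    lapply(stats::setNames(nm = hubs), function(m) "consensus_centrality")),
    table = tab,
    means = attr(tab, "means")
  ), class = "hub_result")
}

#' @export
print.hub_result <- function(x, ...) {
  cat(sprintf("<hub_result> %d/%d nodes pass all four centrality means\n",
              length(x$hubs$members), nrow(x$table)))
  if (length(x$hubs$members)) cat(" ", paste(x$hubs$members, collapse = ", "), "\n")
  invisible(x)
}

#' Write a centrality table as TSV
#'
#' @param tab A `centrality_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centrality_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
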