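# MCODE molecular-complex detection: k-core-based vertex weighting, greedy
# complex growth from high-weight seeds, and 2-core/haircut post-processing.

#' MCODE parameters
#'
#' Defaults mirror the Cytoscape MCODE plugin's documented defaults.
#'
#' @param include_loops Count self-loops in scoring (unsupported; must stay
#'   `FALSE`).
#' @param degree_cutoff Minimum degree for a node to receive a non-zero
#'   weight (default 2).
#' @param node_score_cutoff Fractional weight tolerance for admitting a
#'   neighbor during complex growth (default 0.2): a neighbor joins when its
#'   weight is strictly greater than `w(seed) * (1 - node_score_cutoff)`.
#' @param haircut Iteratively remove degree-1 nodes from a predicted complex
#'   (default `TRUE`).
#' @param fluff Overlapping-complex expansion; not supported, must stay
#'   `FALSE`.
#' @param fluff_density Fluff density threshold (kept for config
#'   compatibility).
#' @param k_core Complexes lacking a k-core are discarded (default 2).
#' @param max_depth Maximum breadth-first growth depth from the seed
#'   (default 100).
#' @return An `mcode_params` list.
#' @export
mcode_params <- function(include_loops = FALSE, degree_cutoff = 2L,
                         node_score_cutoff = 0.2, haircut = TRUE,
                         fluff = FALSE, fluff_density = 0.1,
                         k_core = 2L, max_depth = 100L) {
  if (isTRUE(include_loops)) {
    np_stop("include_loops = TRUE is not supported", "netpharm_unsupported_error")
  }
  if (isTRUE(fluff)) {
    np_stop("fluff mode is not supported", "netpharm_unsupported_error")
  }
  assert_scalar_number(degree_cutoff, "degree_cutoff", 0, Inf)
  assert_scalar_number(node_score_cutoff, "node_score_cutoff", 0, 1)
  assert_scalar_number(fluff_density, "fluff_density", 0, 1)
  assert_scalar_number(k_core, "k_core", 0, Inf)
  assert_scalar_number(max_depth, "max_depth", 1, Inf)
  structure(list(include_loops = FALSE, degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff, haircut = isTRUE(haircut),
                 fluff = FALSE, fluff_density = fluff_density,
                 k_core = as.integer(k_core), max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

graph_density_simple <- function(n, e) {
  if (n < 2L) return(0)
  2 * e / (n * (n - 1))
}

# density of the highest k-core of a subgraph, times its core number
highest_core_weight <- function(sub) {
  core <- igraph::coreness(sub)
  kmax <- max(core)
  keep <- which(core == kmax)
  core_sub <- igraph::induced_subgraph(sub, keep)
  kmax * graph_density_simple(igraph::vcount(core_sub), igraph::ecount(core_sub))
}

#' MCODE vertex weights
#'
#' `w(v) = k * density(highest k-core of the closed neighborhood N[v])`.
#' Nodes with degree below `degree_cutoff` are weighted 0 and never seed or
#' join a complex.
#'
#' @param g igraph object.
#' @param params An [mcode_params()] object.
#' @return Named numeric vector of non-negative weights.
#' @export
mcode_vertex_weights <- function(g, params = mcode_params()) {
  n <- igraph::vcount(g)
  out <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (n == 0L) return(out)
  deg <- igraph::degree(g, loops = FALSE)
  adj <- igraph::as_adj_list(g, mode = "all", loops = "ignore", multiple = FALSE)
  for (i in seq_len(n)) {
    if (deg[[i]] < params$degree_cutoff) next
    closed <- c(i, as.integer(adj[[i]]))
    out[[i]] <- highest_core_weight(igraph::induced_subgraph(g, closed))
  }
  out
}

haircut_nodes <- function(sub_adj, keep) {
  # iteratively drop nodes with < 2 neighbors inside `keep`
  repeat {
    deg_in <- vapply(keep, function(v) sum(sub_adj[[v]] %in% keep), integer(1))
    drop <- keep[deg_in < 2L]
    if (!length(drop)) return(keep)
    keep <- setdiff(keep, drop)
    if (!length(keep)) return(keep)
  }
}

#' Predict molecular complexes (MCODE)
#'
#' Grows complexes greedily from the highest-weight unassigned seed,
#' admitting unassigned neighbors whose weight is strictly greater than
#' `w(seed) * (1 - node_score_cutoff)`, breadth-limited by `max_depth`.
#' Complexes are node-disjoint. Post-processing discards complexes lacking a
#' `k_core`-core and (when `haircut`) iteratively removes degree-1 nodes;
#' the score `density * size` is computed after post-processing. Results
#' are ranked by descending score, breaking ties by size then seed name.
#'
#' @param g igraph object.
#' @param params An [mcode_params()] object.
#' @return An object of class `mcode_result`: a list of modules, each with
#'   `nodes` (character), `seed`, `score`, `density`, `size` and `rank`.
#' @export
mcode <- function(g, params = mcode_params()) {
  n <- igraph::vcount(g)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- sprintf("V%d", seq_len(n))
  }
  names_v <- igraph::V(g)$name
  w <- mcode_vertex_weights(g, params)
  adj <- lapply(igraph::as_adj_list(g, mode = "all", loops = "ignore",
                                    multiple = FALSE), as.integer)
  assigned <- logical(n)
  order_seeds <- order(-w, names_v)
  complexes <- list()

  for (s in order_seeds) {
    if (assigned[s] || w[[s]] <= 0) next
    threshold <- w[[s]] * (1 - params$node_score_cutoff)
    members <- s
    assigned[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer()
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!assigned[u] && w[[u]] > threshold) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    complexes[[length(complexes) + 1L]] <- list(seed = s, members = members)
  }

  modules <- list()
  for (cx in complexes) {
    sub <- igraph::induced_subgraph(g, cx$members)
    if (igraph::vcount(sub) < 2L) next
    if (max(igraph::coreness(sub)) < params$k_core) next
    keep <- seq_len(igraph::vcount(sub))
    if (params$haircut) {
      sub_adj <- lapply(igraph::as_adj_list(sub, mode = "all", loops = "ignore",
                                            multiple = FALSE), as.integer)
      keep <- haircut_nodes(sub_adj, keep)
    }
    if (length(keep) < 2L) next
    final <- igraph::induced_subgraph(sub, keep)
    node_names <- igraph::V(final)$name
    seed_name <- names_v[[cx$seed]]
    if (!seed_name %in% node_names) next  # degenerate: seed trimmed away
    dens <- graph_density_simple(igraph::vcount(final), igraph::ecount(final))
    modules[[length(modules) + 1L]] <- list(
      nodes = sort(node_names),
      seed = seed_name,
      score = dens * igraph::vcount(final),
      density = dens,
      size = igraph::vcount(final)
    )
  }

  if (length(modules)) {
    scores <- vapply(modules, `[[`, numeric(1), "score")
    sizes <- vapply(modules, `[[`, numeric(1), "size")
    seeds <- vapply(modules, `[[`, character(1), "seed")
    ord <- order(-scores, -sizes, seeds)
    modules <- modules[ord]
    for (i in seq_along(modules)) modules[[i]]$rank <- i
  }
  structure(modules, class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("<mcode_result> %d modules\n", length(x)))
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.mcode_result <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(rank = integer(), score = numeric(), size = integer(),
                      seed = character(), members = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    rank = vapply(x, `[[`, numeric(1), "rank"),
    score = vapply(x, `[[`, numeric(1), "score"),
    size = vapply(x, `[[`, numeric(1), "size"),
    seed = vapply(x, `[[`, character(1), "seed"),
    members = vapply(x, function(m) paste(m$nodes, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write MCODE modules as TSV
#'
#' @param x An `mcode_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modules_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
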