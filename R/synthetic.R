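# Synthetic planted-structure fixtures with recorded ground truth.  The
# generators stand in for database exports: per-source target sets with
# exact region counts, PPI graphs with planted cliques and hubs over a
# sparse background, association networks with planted associates, and
# gene-set libraries with planted enriched terms.  All randomness is
# integer-seeded; region specifications are constructive (exact), not
# probabilistic, so downstream recovery tests are sharp.

#' Generate a synthetic gene universe
#'
#' @param n Number of symbols (>= 1).
#' @param seed Seed (kept for API symmetry; symbol construction is
#'   deterministic).
#' @return Character vector `G000001 ... G<n>`.
#' @export
gen_universe <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    np_validation_error("'n' must be a positive integer")
  }
  sprintf("G%06d", seq_len(as.integer(n)))
}

close_signature <- function(labels, nested) {
  repeat {
    add <- unique(stats::na.omit(unname(nested[labels])))
    add <- setdiff(add, labels)
    if (!length(add)) return(sort(labels))
    labels <- c(labels, add)
  }
}

nesting_depth <- function(label, nested) {
  d <- 0L
  while (!is.na(nested[label])) {
    label <- nested[[label]]
    d <- d + 1L
  }
  d
}

#' Generate target sets with exact overlap structure
#'
#' Builds one [gene_set] per entity with the requested total sizes, exact
#' overlap-region counts, optional nesting (every gene of an inner set also
#' belongs to its outer set), and disjoint exclusive remainders drawn from
#' the universe. Region counts are realized constructively, so a Venn over
#' the generated sets reproduces them exactly.
#'
#' @param universe Character vector of available symbols.
#' @param sizes Named integer vector: entity label -> total set size.
#' @param overlaps Named numeric vector/list: `&`-joined label signatures ->
#'   number of genes lying in exactly those sets (plus any sets implied by
#'   nesting).
#' @param nested Optional named character vector `inner = "outer"` declaring
#'   containment constraints.
#' @param seed RNG seed for the universe shuffle.
#' @return List with `sets` (named list of [gene_set]s) and `truth`
#'   (`seed`, `regions`: named list of gene vectors keyed by closed
#'   signature, `sizes`).
#' @export
gen_target_sets <- function(universe, sizes, overlaps = list(), nested = NULL,
                            seed = 1L) {
  labels <- names(sizes)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    np_validation_error("'sizes' must be a uniquely named vector")
  }
  nested <- nested %||% stats::setNames(character(), character())
  if (length(nested)) {
    if (!all(c(names(nested), nested) %in% labels)) {
      np_validation_error("'nested' refers to unknown set labels")
    }
  }
  nested_lookup <- stats::setNames(rep(NA_character_, length(labels)), labels)
  nested_lookup[names(nested)] <- nested

  region_counts <- stats::setNames(numeric(0), character())
  add_region <- function(sig_labels, count) {
    key <- signature_key(close_signature(sig_labels, nested_lookup))
    cur <- if (key %in% names(region_counts)) region_counts[[key]] else 0
    region_counts[key] <<- cur + count
  }
  ov <- unlist(overlaps)
  for (i in seq_along(ov)) {
    sig_labels <- strsplit(names(ov)[[i]], "&", fixed = TRUE)[[1L]]
    if (!all(sig_labels %in% labels)) {
      np_validation_error(sprintf("overlap '%s' refers to unknown set labels",
                                  names(ov)[[i]]))
    }
    add_region(sig_labels, ov[[i]])
  }
  allocated_in <- function(label) {
    sigs <- strsplit(names(region_counts), "&", fixed = TRUE)
    sum(region_counts[vapply(sigs, function(s) label %in% s, logical(1))])
  }
  depths <- vapply(labels, nesting_depth, integer(1), nested = nested_lookup)
  for (lab in labels[order(-depths)]) {
    rem <- sizes[[lab]] - allocated_in(lab)
    if (rem < 0) {
      np_stop(sprintf(
        "unsatisfiable spec: set '%s' has size %d but %d genes already allocated",
        lab, sizes[[lab]], allocated_in(lab)), "netpharm_unsatisfiable_error")
    }
    if (rem > 0) add_region(lab, rem)
  }
  total <- sum(region_counts)
  if (total > length(universe)) {
    np_stop(sprintf("unsatisfiable spec: %d genes required, universe has %d",
                    total, length(universe)), "netpharm_unsatisfiable_error")
  }
  pool <- with_seed(seed, sample(universe, total))
  keys <- sort(names(region_counts))
  regions <- list()
  offset <- 0L
  for (key in keys) {
    cnt <- as.integer(region_counts[[key]])
    regions[[key]] <- sort(pool[seq_len(cnt) + offset])
    offset <- offset + cnt
  }
  sets <- lapply(stats::setNames(nm = labels), function(lab) {
    sigs <- strsplit(names(regions), "&", fixed = TRUE)
    members <- unlist(regions[vapply(sigs, function(s) lab %in% s, logical(1))],
                      use.names = FALSE)
    gene_set(lab, members,
             lapply(stats::setNames(nm = members), function(m) "synthetic"))
  })
  list(sets = sets,
       truth = list(seed = seed, regions = regions,
                    sizes = vapply(sets, function(s) length(s$members), integer(1)),
                    nested = nested))
}

#' Generate a PPI graph with planted cliques and hubs
#'
#' Planted modules are fully wired cliques with confidence weights drawn
#' from U(0.7, 1), so a 0.7 confidence filter never removes a planted edge.
#' Hub nodes are attached to every member of `hub_cliques` planted cliques
#' (at confidence >= 0.7), giving them top degree, MNC, MCC and EPC. The
#' background is an Erdős–Rényi layer at `background_p` with weights from
#' U(0.4, 1). Two constraints keep the recorded ground truth exact under
#' the downstream algorithms: edges between two background nodes must form
#' a forest (a background cycle is a 2-core, i.e. a spurious module), and
#' planted hubs are never made adjacent to each other (a hub-hub edge
#' merges their attached cliques into larger maximal cliques, inflating
#' every clique member's MCC past the planted hubs'). Isolated nodes either
#' carry no edges (`"bare"`) or only sub-threshold edges
#' (`"low_conf"`, weight < 0.7) that vanish under the default filter.
#'
#' @param n_background Number of background filler nodes.
#' @param module_sizes Integer vector of planted clique sizes.
#' @param n_hubs Number of planted hub nodes (requires >= 3 planted
#'   cliques).
#' @param background_p Background edge probability (default 0.05).
#' @param n_isolated Number of nodes destined to drop out as isolates.
#' @param isolated_mode `"bare"` (degree 0) or `"low_conf"` (only edges with
#'   weight < 0.7).
#' @param hub_cliques Number of cliques each hub attaches to (default 3).
#' @param node_names Optional character vector supplying node names (length
#'   >= total nodes); defaults to [gen_universe()] symbols.
#' @param seed RNG seed.
#' @return List with `graph` (weighted igraph) and `truth` (`seed`,
#'   `planted_modules`, `planted_hubs`, `isolated`, `background`).
#' @export
gen_ppi <- function(n_background, module_sizes = integer(), n_hubs = 0L,
                    background_p = 0.05, n_isolated = 0L,
                    isolated_mode = c("bare", "low_conf"),
                    hub_cliques = 3L, node_names = NULL, seed = 1L) {
  isolated_mode <- match.arg(isolated_mode)
  assert_scalar_number(background_p, "background_p", 0, 1)
  if (n_hubs > 0 && length(module_sizes) < hub_cliques) {
    np_validation_error(sprintf(
      "planting hubs requires at least %d cliques; got %d",
      hub_cliques, length(module_sizes)))
  }
  n_total <- sum(module_sizes) + n_hubs + n_background + n_isolated
  nm <- node_names %||% gen_universe(max(n_total, 1L))
  if (length(nm) < n_total) {
    np_validation_error("'node_names' shorter than the total node count")
  }
  nm <- nm[seq_len(n_total)]
  idx <- 0L
  take <- function(k) {
    out <- nm[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  modules <- lapply(module_sizes, take)
  hubs <- take(n_hubs)
  background <- take(n_background)
  isolated <- take(n_isolated)

  edges <- list()
  push <- function(a, b, w) edges[[length(edges) + 1L]] <<- data.frame(
    a = a, b = b, w = w, stringsAsFactors = FALSE)

  with_seed(seed, {
    for (mod in modules) {
      if (length(mod) >= 2L) {
        pr <- utils::combn(mod, 2L)
        push(pr[1L, ], pr[2L, ], stats::runif(ncol(pr), 0.7, 1))
      }
    }
    for (h in hubs) {
      att <- unlist(modules[seq_len(hub_cliques)])
      push(rep(h, length(att)), att, stats::runif(length(att), 0.7, 1))
    }
    # background layer: forest among background nodes, free elsewhere
    connectable <- c(unlist(modules), hubs, background)
    is_bg <- stats::setNames(connectable %in% background, connectable)
    bg_index <- stats::setNames(seq_along(background), background)
    bg_parent <- seq_along(background)
    bg_find <- function(i) {
      while (bg_parent[[i]] != i) i <- bg_parent[[i]]
      i
    }
    same_clique <- stats::setNames(rep(NA_integer_, length(connectable)), connectable)
    for (j in seq_along(modules)) same_clique[modules[[j]]] <- j
    hubset <- hubs
    nconn <- length(connectable)
    if (nconn >= 2L && background_p > 0) {
      for (i in seq_len(nconn - 1L)) {
        for (j in seq.int(i + 1L, nconn)) {
          a <- connectable[[i]]; b <- connectable[[j]]
          ca <- same_clique[[a]]; cb <- same_clique[[b]]
          if (!is.na(ca) && !is.na(cb) && ca == cb) next  # already wired
          if ((a %in% hubset && !is.na(cb) && cb <= hub_cliques) ||
              (b %in% hubset && !is.na(ca) && ca <= hub_cliques)) next
          if (a %in% hubset && b %in% hubset) next  # hubs stay non-adjacent
          if (stats::runif(1) > background_p) next
          if (is_bg[[a]] && is_bg[[b]]) {
            ra <- bg_find(bg_index[[a]]); rb <- bg_find(bg_index[[b]])
            if (ra == rb) next  # would close a background cycle
            bg_parent[[ra]] <- rb
          }
          push(a, b, stats::runif(1, 0.4, 1))
        }
      }
    }
    if (isolated_mode == "low_conf" && length(isolated) && length(connectable)) {
      anchors <- connectable[1L + (seq_along(isolated) - 1L) %% length(connectable)]
      push(isolated, anchors, stats::runif(length(isolated), 0.4, 0.699))
    }
  })

  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), w = numeric())
  g <- as_weighted_graph(edf, extra_nodes = nm)
  list(graph = g,
       truth = list(seed = seed, planted_modules = modules,
                    planted_hubs = hubs, isolated = isolated,
                    background = background))
}

#' Generate a functional-association network with planted associates
#'
#' Each planted associate connects to at least `min_seed_links` seed genes
#' with strong weights (U(0.6, 1)); background genes connect to at most one
#' seed with a weak weight (U(0.1, 0.5)), so the degree-normalized
#' seed-connectivity score separates associates from background by
#' construction. Seeds are chained together with neutral edges so every
#' seed is present in the network.
#'
#' @param seeds Character vector (or [gene_set]) of seed genes.
#' @param n_associates Number of planted associate genes (default 20).
#' @param n_background Number of background genes (default 30).
#' @param min_seed_links Minimum seed links per associate (default 3).
#' @param associate_names,background_names Optional name vectors.
#' @param seed RNG seed.
#' @return List with `graph` (weighted igraph) and `truth`
#'   (`planted_associates`, `seed`).
#' @export
gen_association <- function(seeds, n_associates = 20L, n_background = 30L,
                            min_seed_links = 3L, associate_names = NULL,
                            background_names = NULL, seed = 1L) {
  if (inherits(seeds, "gene_set")) seeds <- seeds$members
  seeds <- unique(as.character(seeds))
  if (length(seeds) < min_seed_links) {
    np_validation_error("need at least 'min_seed_links' seed genes")
  }
  assoc <- associate_names %||% sprintf("ASSOC%03d", seq_len(n_associates))
  bg <- background_names %||% sprintf("BGN%03d", seq_len(n_background))
  edges <- list()
  push <- function(a, b, w) edges[[length(edges) + 1L]] <<- data.frame(
    a = a, b = b, w = w, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (g1 in assoc) {
      kk <- sample_vec(seq.int(min_seed_links,
                               min(min_seed_links + 2L, length(seeds))), 1L)
      tgt <- sample_vec(seeds, kk)
      push(rep(g1, kk), tgt, stats::runif(kk, 0.6, 1))
    }
    for (g1 in bg) {
      if (stats::runif(1) < 0.7) {
        push(g1, sample_vec(seeds, 1L), stats::runif(1, 0.1, 0.5))
      }
    }
    if (length(seeds) >= 2L) {
      push(seeds[-length(seeds)], seeds[-1L],
           stats::runif(length(seeds) - 1L, 0.3, 0.6))
    }
  })
  edf <- do.call(rbind, edges)
  g <- as_weighted_graph(edf, extra_nodes = c(seeds, assoc, bg))
  list(graph = g, truth = list(seed = seed, planted_associates = sort(assoc)))
}

#' Generate a gene-set library with planted enriched terms
#'
#' Random terms are drawn uniformly from the universe; planted terms are
#' included verbatim so a designated query is over-represented in them by
#' construction.
#'
#' @param universe Character vector of background genes.
#' @param n_terms Number of random terms.
#' @param term_size_range Length-2 integer vector of term sizes (inclusive).
#' @param planted Named list of character vectors appended verbatim as
#'   terms; genes must belong to the universe.
#' @param name Library name.
#' @param seed RNG seed.
#' @return List with `library` (a `gene_set_library`) and `truth`
#'   (`enriched_terms`, `seed`).
#' @export
gen_library <- function(universe, n_terms = 20L, term_size_range = c(5L, 50L),
                        planted = list(), name = "synthetic_library",
                        seed = 1L) {
  if (term_size_range[[2L]] > length(universe)) {
    np_validation_error("term sizes exceed the universe size")
  }
  if (length(planted)) {
    stray <- setdiff(unlist(planted), universe)
    if (length(stray)) {
      np_validation_error(sprintf("planted genes outside the universe: %s",
                                  paste(utils::head(stray, 3L), collapse = ", ")))
    }
  }
  terms <- with_seed(seed, {
    szs <- sample_vec(seq.int(term_size_range[[1L]], term_size_range[[2L]]),
                      n_terms, replace = TRUE)
    stats::setNames(lapply(szs, function(k) sample_vec(universe, k)),
                    sprintf("T%03d", seq_len(n_terms)))
  })
  if (length(planted)) {
    if (any(names(planted) %in% names(terms))) {
      np_validation_error("planted term names clash with generated term names")
    }
    terms <- c(terms, planted)
  }
  list(library = gene_set_library(name, terms, universe = universe),
       truth = list(seed = seed, enriched_terms = names(planted)))
}

#' Verify a fixture's recorded ground truth against its artifact
#'
#' Checks every claim a generator records: planted cliques are fully wired
#' at confidence >= 0.7, hubs attach to their cliques, isolates are
#' disconnected (or sub-threshold), realized target-set regions are exact
#' and nesting holds, and planted library terms exist with their genes.
#' Fails with a `netpharm_truth_error` on any violation.
#'
#' @param fixture A list returned by [gen_target_sets()], [gen_ppi()],
#'   [gen_association()] or [gen_library()].
#' @return `TRUE`, invisibly.
#' @export
verify_fixture <- function(fixture) {
  truth <- fixture$truth
  fail <- function(msg) np_stop(msg, "netpharm_truth_error")
  if (!is.null(fixture$graph) && !is.null(truth$planted_modules)) {
    g <- fixture$graph
    for (mod in truth$planted_modules) {
      if (!all(mod %in% igraph::V(g)$name)) fail("planted module node missing")
      if (length(mod) >= 2L) {
        pr <- utils::combn(mod, 2L)
        for (j in seq_len(ncol(pr))) {
          eid <- igraph::get_edge_ids(g, pr[, j])
          if (eid == 0) fail("planted clique edge missing")
          if (igraph::E(g)$weight[eid] < 0.7) fail("planted edge below 0.7")
        }
      }
    }
    for (h in truth$planted_hubs) {
      nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, h))]
      hit <- vapply(truth$planted_modules, function(mod) all(mod %in% nb),
                    logical(1))
      if (sum(hit) < min(3L, length(truth$planted_modules))) {
        fail("planted hub not attached to enough cliques")
      }
    }
    filt <- drop_isolated(filter_confidence(g, 0.7))
    if (any(truth$isolated %in% igraph::V(filt)$name)) {
      fail("isolate survives the confidence filter")
    }
  }
  if (!is.null(fixture$sets)) {
    for (key in names(truth$regions)) {
      sig <- strsplit(key, "&", fixed = TRUE)[[1L]]
      for (gene in truth$regions[[key]]) {
        inside <- vapply(fixture$sets,
                         function(s) gene %in% s$members, logical(1))
        if (!setequal(names(fixture$sets)[inside], sig)) {
          fail(sprintf("gene %s not realized in region %s", gene, key))
        }
      }
    }
    for (inner in names(truth$nested)) {
      rep_ <- containment_report(fixture$sets[[inner]],
                                 fixture$sets[[truth$nested[[inner]]]])
      if (!rep_$is_subset) fail("nesting constraint violated")
    }
  }
  if (!is.null(fixture$library)) {
    for (tn in truth$enriched_terms) {
      if (is.null(fixture$library$terms[[tn]])) fail("planted term missing")
    }
  }
  if (!is.null(fixture$graph) && !is.null(truth$planted_associates)) {
    if (!all(truth$planted_associates %in% igraph::V(fixture$graph)$name)) {
      fail("planted associate missing from network")
    }
  }
  invisible(TRUE)
}
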