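# Drug-target-disease tripartite networks: typed nodes (drug, disease,
# target), membership edges only between an entity and a target, and
# GraphML / SIF / Cytoscape-JSON exporters.

#' Build a drug-target-disease network
#'
#' Creates one node per drug, per disease and per target, and one edge per
#' (entity, target) membership. Targets present in `all_targets` but in no
#' entity set remain as isolated nodes (set `keep_isolated = FALSE` to drop
#' them).
#'
#' @param drug_targets Named list of [gene_set]s, one per drug; every member
#'   must belong to `all_targets`.
#' @param disease_targets Named list of [gene_set]s, one per disease; same
#'   constraint.
#' @param all_targets [gene_set] of all target nodes to create.
#' @param keep_isolated Keep targets linked to no entity (default `TRUE`).
#' @return An object of class `tripartite_network` with data frames `nodes`
#'   (`name`, `kind`) and `edges` (`entity`, `target`, `relation`).
#' @export
build_tripartite <- function(drug_targets, disease_targets, all_targets,
                             keep_isolated = TRUE) {
  check_entities <- function(lst, what) {
    if (length(lst) && (is.null(names(lst)) || anyDuplicated(names(lst)))) {
      np_validation_error(sprintf("%s names must be unique", what))
    }
    offenders <- character()
    for (nm in names(lst)) {
      stray <- setdiff(lst[[nm]]$members, all_targets$members)
      if (length(stray)) {
        offenders <- c(offenders, sprintf("%s: %s", nm, paste(stray, collapse = ",")))
      }
    }
    if (length(offenders)) {
      np_validation_error(paste0(
        what, " sets contain targets outside 'all_targets' — ",
        paste(offenders, collapse = "; ")))
    }
  }
  check_entities(drug_targets, "drug")
  check_entities(disease_targets, "disease")

  edges <- data.frame(entity = character(), target = character(),
                      relation = character(), stringsAsFactors = FALSE)
  for (nm in names(drug_targets)) {
    m <- drug_targets[[nm]]$members
    if (length(m)) {
      edges <- rbind(edges, data.frame(entity = nm, target = m,
                                       relation = "targets"))
    }
  }
  for (nm in names(disease_targets)) {
    m <- disease_targets[[nm]]$members
    if (length(m)) {
      edges <- rbind(edges, data.frame(entity = nm, target = m,
                                       relation = "associated_with"))
    }
  }
  targets <- all_targets$members
  if (!keep_isolated) targets <- intersect(targets, edges$target)
  node_block <- function(nms, kind) {
    nms <- nms %||% character()
    data.frame(name = nms, kind = rep(kind, length(nms)),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    node_block(names(drug_targets), "drug"),
    node_block(names(disease_targets), "disease"),
    node_block(targets, "target")
  )
  structure(list(nodes = nodes, edges = edges), class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat(sprintf("<tripartite_network> %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Common targets across all drugs
#'
#' Intersects the target sets of every drug (at least two required),
#' optionally restricted to a reference set such as the related targets.
#'
#' @param drug_targets Named list of [gene_set]s, one per drug.
#' @param restrict_to Optional [gene_set] the intersection is intersected
#'   with.
#' @param label Label of the returned set.
#' @return A [gene_set].
#' @export
common_targets <- function(drug_targets, restrict_to = NULL,
                           label = "common_targets") {
  if (length(drug_targets) < 2L) {
    np_validation_error("common_targets requires at least 2 drugs")
  }
  common <- Reduce(intersect, lapply(drug_targets, `[[`, "members"))
  if (!is.null(restrict_to)) common <- intersect(common, restrict_to$members)
  gene_set(label, common,
           lapply(stats::setNames(nm = common), function(m) names(drug_targets)))
}

tripartite_igraph <- function(net) {
  # vertex ids are kind:name so a gene may share a label with an entity
  ids <- paste(net$nodes$kind, net$nodes$name, sep = ":")
  vdf <- data.frame(name = ids, label = net$nodes$name, kind = net$nodes$kind,
                    stringsAsFactors = FALSE)
  if (nrow(net$edges)) {
    ekind <- ifelse(net$edges$relation == "targets", "drug", "disease")
    edf <- data.frame(from = paste(ekind, net$edges$entity, sep = ":"),
                      to = paste("target", net$edges$target, sep = ":"),
                      relation = net$edges$relation, stringsAsFactors = FALSE)
  } else {
    edf <- data.frame(from = character(), to = character(),
                      relation = character())
  }
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Export a tripartite network
#'
#' GraphML carries a `kind` node attribute and round-trips through
#' [import_tripartite()]; SIF writes one `entity relation target` line per
#' edge plus bare lines for isolated targets; JSON emits a
#' Cytoscape-compatible elements document.
#'
#' @param net A `tripartite_network`.
#' @param path Output path.
#' @param format One of `"graphml"`, `"sif"`, `"json"`.
#' @return `path`, invisibly.
#' @export
export_tripartite <- function(net, path, format = c("graphml", "sif", "json")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) np_validation_error(
                       sprintf("unknown export format '%s'", format[[1L]])))
  if (format == "graphml") {
    igraph::write_graph(tripartite_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    lines <- character()
    if (nrow(net$edges)) {
      lines <- paste(net$edges$entity, net$edges$relation, net$edges$target)
    }
    linked <- unique(net$edges$target)
    iso <- setdiff(net$nodes$name[net$nodes$kind == "target"], linked)
    writeLines(c(lines, iso), path)
  } else {
    elements <- list(
      nodes = lapply(seq_len(nrow(net$nodes)), function(i) {
        list(data = list(
          id = paste(net$nodes$kind[i], net$nodes$name[i], sep = ":"),
          name = net$nodes$name[i], kind = net$nodes$kind[i]))
      }),
      edges = lapply(seq_len(nrow(net$edges)), function(i) {
        ekind <- if (net$edges$relation[i] == "targets") "drug" else "disease"
        list(data = list(
          source = paste(ekind, net$edges$entity[i], sep = ":"),
          target = paste("target", net$edges$target[i], sep = ":"),
          interaction = net$edges$relation[i]))
      })
    )
    jsonlite::write_json(list(elements = elements), path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Import a tripartite network written by [export_tripartite()]
#'
#' @param path Input path.
#' @param format `"graphml"` or `"json"` (SIF drops the kind attribute and
#'   is not round-trippable).
#' @return A `tripartite_network`.
#' @export
import_tripartite <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(name = igraph::V(g)$label, kind = igraph::V(g)$kind,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    rel <- igraph::E(g)$relation
    strip <- function(x) sub("^[a-z]+:", "", x)
    ent_first <- !startsWith(el[, 1L], "target:")
    edges <- data.frame(
      entity = strip(ifelse(ent_first, el[, 1L], el[, 2L])),
      target = strip(ifelse(ent_first, el[, 2L], el[, 1L])),
      relation = rel, stringsAsFactors = FALSE
    )
  } else {
    doc <- jsonlite::read_json(path)
    nodes <- do.call(rbind, lapply(doc$elements$nodes, function(nd) {
      data.frame(name = nd$data$name, kind = nd$data$kind,
                 stringsAsFactors = FALSE)
    }))
    edges <- if (length(doc$elements$edges)) {
      do.call(rbind, lapply(doc$elements$edges, function(ed) {
        data.frame(entity = sub("^[a-z]+:", "", ed$data$source),
                   target = sub("^[a-z]+:", "", ed$data$target),
                   relation = ed$data$interaction, stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(entity = character(), target = character(),
                 relation = character())
    }
  }
  kind_order <- match(nodes$kind, c("drug", "disease", "target"))
  nodes <- nodes[order(kind_order, nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "tripartite_network")
}
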