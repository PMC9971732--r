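# Weighted PPI graphs: STRING-export TSV reading, confidence filtering,
# isolate removal, statistics and writers.  Graphs are undirected simple
# igraph objects with vertex `name` and edge `weight` in [0, 1].

as_weighted_graph <- function(edges_df, extra_nodes = character()) {
  # collapse duplicate / reversed pairs keeping the maximum weight; drop loops
  a <- as.character(edges_df[[1L]])
  b <- as.character(edges_df[[2L]])
  w <- as.numeric(edges_df[[3L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (length(key)) {
    wmax <- tapply(w, key, max)
    pairs <- do.call(rbind, strsplit(names(wmax), "\r", fixed = TRUE))
    el <- data.frame(from = pairs[, 1L], to = pairs[, 2L],
                     weight = as.numeric(wmax), stringsAsFactors = FALSE)
  } else {
    el <- data.frame(from = character(), to = character(), weight = numeric())
  }
  nodes <- sort(unique(c(el$from, el$to, extra_nodes)))
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Read a STRING-style weighted edge list
#'
#' Parses a TSV/whitespace-delimited export with two node columns and a
#' combined-score column.  A header line is detected automatically (the
#' score field fails numeric parsing); comment lines starting with `#` are
#' tolerated unless they are a commented header.  Duplicate and reversed
#' pairs collapse to a single edge keeping the maximum weight; self-loops
#' are dropped.
#'
#' @param path Input file.
#' @param score_scale `"auto"`, `"unit"` or `"milli"`. STRING exports its
#'   combined score in 0–1000 ("milli"); `"auto"` divides by 1000 iff any
#'   score exceeds 1, so both dialects parse to weights in \[0, 1\].
#' @param node_cols Length-2 integer or character vector locating the node
#'   columns (default first two columns).
#' @param score_col Integer or character locating the score column; default
#'   `"auto"` uses the column named `combined_score` when present, else the
#'   last column.
#' @return An undirected simple igraph with edge attribute `weight`.
#' @export
read_edge_tsv <- function(path, score_scale = c("auto", "unit", "milli"),
                          node_cols = c(1L, 2L), score_col = "auto") {
  score_scale <- match.arg(score_scale)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    np_stop("empty edge file", "netpharm_parse_error")
  }
  split_row <- function(x) strsplit(trimws(sub("^#", "", x)), "[\t ]+")[[1L]]
  first <- split_row(lines[[1L]])
  if (length(first) < 3L) {
    np_stop("edge file needs at least 3 columns (node1, node2, score)",
            "netpharm_parse_error")
  }
  header <- NULL
  # header iff the last field of line 1 is not numeric
  if (is.na(suppressWarnings(as.numeric(first[[length(first)]])))) {
    header <- first
    lines <- lines[-1L]
  }
  lines <- lines[!startsWith(trimws(lines), "#")]

  col_index <- function(spec, default) {
    if (identical(spec, "auto")) return(default)
    if (is.character(spec)) {
      if (is.null(header)) {
        np_stop(sprintf("column '%s' requested but file has no header",
                        paste(spec, collapse = ",")), "netpharm_parse_error")
      }
      idx <- match(spec, header)
      if (any(is.na(idx))) {
        np_stop(sprintf("missing column(s): %s",
                        paste(spec[is.na(idx)], collapse = ", ")),
                "netpharm_parse_error")
      }
      return(idx)
    }
    as.integer(spec)
  }
  ncols <- length(first)
  sdefault <- if (!is.null(header) && "combined_score" %in% header) {
    match("combined_score", header)
  } else ncols
  sc <- col_index(score_col, sdefault)
  nc <- if (is.character(node_cols)) col_index(node_cols, NULL) else as.integer(node_cols)

  rows <- lapply(seq_along(lines), function(i) {
    f <- split_row(lines[[i]])
    lineno <- i + if (is.null(header)) 0L else 1L
    if (length(f) < max(c(nc, sc))) {
      np_stop(sprintf("malformed row at line %d: expected >= %d fields, got %d",
                      lineno, max(c(nc, sc)), length(f)), "netpharm_parse_error")
    }
    w <- suppressWarnings(as.numeric(f[[sc]]))
    if (is.na(w)) {
      np_stop(sprintf("malformed row at line %d: score '%s' is not numeric",
                      lineno, f[[sc]]), "netpharm_parse_error")
    }
    c(f[[nc[[1L]]]], f[[nc[[2L]]]], w)
  })
  m <- do.call(rbind, rows)
  df <- data.frame(a = toupper(m[, 1L]), b = toupper(m[, 2L]),
                   w = as.numeric(m[, 3L]), stringsAsFactors = FALSE)
  if (score_scale == "milli" || (score_scale == "auto" && any(df$w > 1))) {
    df$w <- df$w / 1000
  }
  if (any(df$w < 0 | df$w > 1)) {
    np_stop("scores outside [0,1] after scaling; check score_scale",
            "netpharm_parse_error")
  }
  as_weighted_graph(df)
}

#' Filter edges by interaction confidence
#'
#' Keeps edges whose weight is greater than or equal to `threshold` (the
#' STRING "high confidence 0.700" cut is inclusive).  The node set is left
#' untouched; call [drop_isolated()] to mimic hiding disconnected nodes.
#'
#' @param g Weighted igraph.
#' @param threshold Confidence cutoff in \[0, 1\]; default 0.7.
#' @return The filtered graph.
#' @export
filter_confidence <- function(g, threshold = 0.7) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  w <- igraph::E(g)$weight
  igraph::delete_edges(g, igraph::E(g)[w < threshold])
}

#' Remove degree-zero nodes
#'
#' @param g igraph object.
#' @return Graph without isolated vertices.
#' @export
drop_isolated <- function(g) {
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

#' Basic graph statistics
#'
#' @param g igraph object.
#' @return List with `n_nodes`, `n_edges` and `n_components`.
#' @export
graph_stats <- function(g) {
  list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_components = igraph::components(g)$no
  )
}

#' Write a weighted edge TSV (node1, node2, score)
#'
#' Inverse of [read_edge_tsv()]; the written file round-trips exactly for
#' graphs with canonical (uppercase) names. Isolated nodes are not
#' representable in an edge list and are omitted.
#'
#' @param g Weighted igraph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(node1 = pmin(el[, 1L], el[, 2L]),
                   node2 = pmax(el[, 1L], el[, 2L]),
                   combined_score = igraph::E(g)$weight)
  df <- df[order(df$node1, df$node2), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph in SIF format
#'
#' @param g igraph object.
#' @param path Output path.
#' @param relation Interaction label placed in the middle column.
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path, relation = "pp") {
  el <- igraph::as_edgelist(g)
  lines <- if (nrow(el)) paste(el[, 1L], relation, el[, 2L]) else character()
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Write a graph in GraphML format
#'
#' Thin wrapper over [igraph::write_graph()] so every exporter lives behind
#' one package surface.
#'
#' @param g igraph object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
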