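# Gene sets: normalized symbol collections with per-gene source provenance.

#' Construct a gene set
#'
#' A `gene_set` is a labeled, deduplicated collection of normalized gene
#' symbols (uppercase, no whitespace) with per-gene provenance recording
#' which source(s) contributed each symbol.
#'
#' @param label Name of the entity the set belongs to (a drug, a disease, or
#'   a derived set such as an intersection).
#' @param members Character vector of gene symbols; deduplicated and sorted.
#' @param provenance Optional named list mapping each member to a character
#'   vector of source names. Members missing from the list are attributed to
#'   `label` itself.
#' @return An object of class `gene_set` with elements `label`, `members`
#'   (sorted unique character vector) and `provenance`.
#' @export
gene_set <- function(label, members = character(), provenance = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    np_validation_error("'label' must be a single non-empty string")
  }
  members <- as.character(members)
  if (any(is.na(members)) || any(!nzchar(members)) || any(grepl("\\s", members))) {
    np_validation_error("gene symbols must be non-empty and contain no whitespace")
  }
  members <- sort(unique(members))
  prov <- stats::setNames(vector("list", length(members)), members)
  for (m in members) {
    src <- provenance[[m]] %||% label
    prov[[m]] <- sort(unique(as.character(src)))
  }
  structure(list(label = label, members = members, provenance = prov),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$label, length(x$members)))
  if (length(x$members)) {
    shown <- utils::head(x$members, 10L)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$members) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Normalize raw gene symbol tokens into a gene set
#'
#' Trims surrounding whitespace, uppercases, applies an optional alias map
#' (e.g. UniProt accession to HGNC symbol), and deduplicates. Tokens absent
#' from the alias map are retained uppercased — set sizes stay conservative —
#' and reported in the `"unmapped"` attribute of the result.
#'
#' @param raw Character vector of raw tokens; may contain duplicates, mixed
#'   case and surrounding whitespace. An empty vector yields an empty set.
#' @param alias_map Optional named character vector or two-column data frame
#'   (alias, symbol) used to rewrite tokens after case folding.
#' @param label Label for the resulting set.
#' @param source Source-database name recorded as provenance for every
#'   member; defaults to `label`.
#' @return A [gene_set] with attribute `"unmapped"` listing tokens that were
#'   kept verbatim because the alias map did not cover them (empty when no
#'   map was supplied).
#' @export
normalize_symbols <- function(raw, alias_map = NULL, label = "gene_set",
                              source = label) {
  raw <- as.character(raw %||% character())
  tokens <- toupper(trimws(raw))
  if (any(is.na(tokens)) || (length(tokens) && any(!nzchar(tokens)))) {
    np_validation_error("input contains tokens that normalize to the empty string")
  }
  unmapped <- character()
  if (!is.null(alias_map)) {
    if (is.data.frame(alias_map)) {
      alias_map <- stats::setNames(as.character(alias_map[[2L]]),
                                   as.character(alias_map[[1L]]))
    }
    names(alias_map) <- toupper(trimws(names(alias_map)))
    alias_map[] <- toupper(trimws(alias_map))
    hit <- tokens %in% names(alias_map)
    unmapped <- sort(unique(tokens[!hit]))
    tokens[hit] <- unname(alias_map[tokens[hit]])
  }
  prov <- lapply(stats::setNames(nm = unique(tokens)), function(m) source)
  out <- gene_set(label, tokens, prov)
  attr(out, "unmapped") <- unmapped
  out
}

#' Aggregate per-source target lists into one gene set
#'
#' Unions target lists retrieved from several source databases for the same
#' entity, eliminating duplicates and recording, for every gene, the full
#' set of sources that contributed it.
#'
#' @param per_source Named list of [gene_set] objects, one per source
#'   database; names are the source names and must be unique.
#' @param label Label of the aggregated set.
#' @return A [gene_set] whose members are the union of all inputs.
#' @export
aggregate_sources <- function(per_source, label) {
  if (!is.list(per_source) || length(per_source) == 0L) {
    np_validation_error("'per_source' must be a non-empty named list of gene sets")
  }
  srcs <- names(per_source)
  if (is.null(srcs) || any(!nzchar(srcs)) || anyDuplicated(srcs)) {
    np_validation_error("source names must be unique and non-empty (clashing labels)")
  }
  prov <- list()
  for (s in srcs) {
    gs <- per_source[[s]]
    if (!inherits(gs, "gene_set")) {
      np_validation_error(sprintf("source '%s' is not a gene_set", s))
    }
    for (m in gs$members) prov[[m]] <- c(prov[[m]], s)
  }
  gene_set(label, names(prov), prov)
}

signature_key <- function(labels) paste(sort(labels), collapse = "&")

#' Venn-region accounting over two to six gene sets
#'
#' Partitions the union of the input sets into the `2^k - 1` disjoint
#' membership regions and returns per-region counts and members, plus the
#' all-sets intersection as a [gene_set].
#'
#' @param sets List of at least two (at most six) [gene_set] objects with
#'   distinct labels.
#' @param intersection_label Label for the returned intersection set.
#' @return An object of class `venn_result`: `labels`, `region_counts`
#'   (named integer vector keyed by `&`-joined label signatures),
#'   `regions` (named list of member vectors) and `intersection`.
#' @export
venn <- function(sets, intersection_label = "intersection") {
  if (!is.list(sets) || length(sets) < 2L) {
    np_validation_error("venn requires at least 2 gene sets")
  }
  if (length(sets) > 6L) {
    np_validation_error("venn supports at most 6 sets")
  }
  labels <- vapply(sets, function(s) {
    if (!inherits(s, "gene_set")) np_validation_error("all inputs must be gene_set objects")
    s$label
  }, character(1))
  if (anyDuplicated(labels)) np_validation_error("set labels must be distinct")

  universe <- sort(unique(unlist(lapply(sets, `[[`, "members"))))
  member_mat <- vapply(sets, function(s) universe %in% s$members,
                       logical(length(universe)))
  if (length(universe) == 1L) member_mat <- matrix(member_mat, nrow = 1L)
  sig <- apply(member_mat, 1L, function(row) signature_key(labels[row]))
  regions <- split(universe, sig)

  # deterministic region order: by signature cardinality, then alphabetically
  all_sigs <- names(regions)
  card <- lengths(strsplit(all_sigs, "&", fixed = TRUE))
  regions <- regions[order(card, all_sigs)]
  counts <- vapply(regions, length, integer(1))

  inter_key <- signature_key(labels)
  inter_genes <- regions[[inter_key]] %||% character()
  prov <- NULL
  if (length(inter_genes)) {
    prov <- lapply(stats::setNames(nm = inter_genes), function(m) {
      sort(unique(unlist(lapply(sets, function(s) s$provenance[[m]]))))
    })
  }
  structure(list(
    labels = labels,
    region_counts = counts,
    regions = regions,
    intersection = gene_set(intersection_label, inter_genes, prov)
  ), class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("<venn_result> %d sets, union %d genes\n",
              length(x$labels), sum(x$region_counts)))
  print(x$region_counts)
  invisible(x)
}

#' Merge an intersection set with its associated-expansion set
#'
#' Unions the drug/disease intersection targets with the functionally
#' associated targets into one related-target set, merging provenance.
#' For disjoint inputs the size is the sum of the input sizes.
#'
#' @param intersection,associated [gene_set] objects.
#' @param label Label of the combined set.
#' @return A [gene_set] containing the union.
#' @export
combine_related <- function(intersection, associated, label = "related") {
  for (gs in list(intersection, associated)) {
    if (!inherits(gs, "gene_set")) np_validation_error("inputs must be gene_set objects")
  }
  members <- union(intersection$members, associated$members)
  prov <- lapply(stats::setNames(nm = members), function(m) {
    c(intersection$provenance[[m]], associated$provenance[[m]])
  })
  gene_set(label, members, prov)
}

#' Report whether one gene set is contained in another
#'
#' @param inner,outer [gene_set] objects.
#' @return A list with `is_subset` (`TRUE` iff every member of `inner` is in
#'   `outer`) and `missing` (a [gene_set] of `inner` members absent from
#'   `outer`).
#' @export
containment_report <- function(inner, outer) {
  miss <- setdiff(inner$members, outer$members)
  prov <- if (length(miss)) inner$provenance[miss] else NULL
  list(
    is_subset = length(miss) == 0L,
    missing = gene_set(paste0(inner$label, "_not_in_", outer$label),
                       miss, prov)
  )
}

# File I/O --------------------------------------------------------------------

#' Read a gene list file (one symbol per line)
#'
#' Lines starting with `#` and blank lines are ignored; remaining tokens are
#' passed through [normalize_symbols()].
#'
#' @param path Path to a UTF-8 text file.
#' @inheritParams normalize_symbols
#' @return A [gene_set].
#' @export
read_gene_list <- function(path, alias_map = NULL, label = basename(path),
                           source = label) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  normalize_symbols(lines, alias_map = alias_map, label = label, source = source)
}

#' Read a two-column alias map (alias TAB symbol)
#'
#' @param path Path to a headerless two-column TSV.
#' @return Named character vector mapping alias to symbol.
#' @export
read_alias_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) np_validation_error("alias map must have two columns")
  stats::setNames(toupper(trimws(df[[2L]])), toupper(trimws(df[[1L]])))
}

#' Write a gene set as a one-symbol-per-line file
#'
#' @param x A [gene_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  writeLines(x$members, path)
  invisible(path)
}

#' Write a Venn summary as JSON and per-region TSV
#'
#' @param v A `venn_result`.
#' @param json_path Path for the JSON summary (`labels`, `region_counts`,
#'   `intersection`); `NULL` to skip.
#' @param tsv_path Path for a region TSV (columns `region`, `gene`); `NULL`
#'   to skip.
#' @return `v`, invisibly.
#' @export
write_venn_summary <- function(v, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      labels = v$labels,
      region_counts = as.list(v$region_counts),
      intersection = v$intersection$members
    ), json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(
      region = rep(names(v$regions), lengths(v$regions)),
      gene = unlist(v$regions, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(v)
}
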