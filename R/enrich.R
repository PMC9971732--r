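# Over-representation analysis (one-sided hypergeometric), BH adjustment,
# odds-ratio ranking, and a permutation normalized-enrichment-score (NES)
# ranking of transcription-factor regulons.  The permutation NES is an
# explicitly labeled substitute statistic with the same ranking semantics
# (NES descending, then target count) as motif/track-based tools.

#' Construct a gene-set library
#'
#' @param name Library name.
#' @param terms Named list mapping term names to character vectors of gene
#'   symbols; every term must be non-empty.
#' @param universe Optional background gene universe; defaults to the union
#'   of all term genes. When supplied it must cover every term gene.
#' @return An object of class `gene_set_library`.
#' @export
gene_set_library <- function(name, terms, universe = NULL) {
  if (!is.list(terms) || length(terms) == 0L || is.null(names(terms)) ||
      any(!nzchar(names(terms)))) {
    np_validation_error("'terms' must be a non-empty named list")
  }
  terms <- lapply(terms, function(x) sort(unique(toupper(as.character(x)))))
  if (any(lengths(terms) == 0L)) {
    np_validation_error("every term must contain at least one gene")
  }
  union_genes <- sort(unique(unlist(terms, use.names = FALSE)))
  if (is.null(universe)) {
    universe <- union_genes
  } else {
    universe <- sort(unique(toupper(as.character(universe))))
    stray <- setdiff(union_genes, universe)
    if (length(stray)) {
      np_validation_error(sprintf(
        "universe does not cover %d term gene(s), e.g. %s",
        length(stray), paste(utils::head(stray, 3L), collapse = ", ")))
    }
  }
  structure(list(name = name, terms = terms, universe = universe),
            class = "gene_set_library")
}

#' Read a GMT gene-set library
#'
#' Standard GMT: one term per line, tab-delimited as
#' `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @param name Library name (defaults to the file name).
#' @param universe Optional background universe, see [gene_set_library()].
#' @return A `gene_set_library`.
#' @export
read_gmt <- function(path, name = basename(path), universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    np_stop(sprintf("malformed GMT line %d: need term, description, >=1 gene",
                    bad[[1L]]), "netpharm_parse_error")
  }
  terms <- stats::setNames(
    lapply(fields, function(f) f[-(1:2)]),
    vapply(fields, `[[`, character(1), 1L)
  )
  gene_set_library(name, terms, universe)
}

#' Write a gene-set library as GMT
#'
#' @param lib A `gene_set_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path) {
  lines <- vapply(names(lib$terms), function(tn) {
    paste(c(tn, "na", lib$terms[[tn]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; values are validated to lie in \[0, 1\] and
#' returned in input order, capped at 1.
#'
#' @param pvals Numeric vector of p-values.
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
      any(pvals < 0) || any(pvals > 1)) {
    np_validation_error("p-values must be numbers in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

odds_ratio_2x2 <- function(k, K, n, N) {
  a <- k
  b <- K - k
  c <- n - k
  d <- N - K - n + k
  if (a == 0) return(0)
  if (b == 0 || c == 0) return(Inf)
  (a * d) / (b * c)
}

#' Over-representation analysis of a query gene set
#'
#' For every term, forms the 2x2 overlap table of the query (restricted to
#' the universe) against the term and computes the one-sided hypergeometric
#' tail `p = P(X >= k)`, the BH q-value over all library terms, and the
#' odds ratio `k*d / ((K-k)(n-k))` (`+Inf` when a denominator cell is zero
#' with `k > 0`; 0 when `k = 0`). Zero-overlap rows are retained with
#' `p = 1` so the BH family size equals the library size.
#'
#' @param query A [gene_set] (or character vector) of query genes.
#' @param library A [gene_set_library()].
#' @param background_n Optional integer overriding the universe size `N`
#'   (e.g. 20000 protein-coding genes); must be at least the universe size.
#' @return A data frame of class `enrichment_result` with one row per term:
#'   `term`, `genes` (overlap, `;`-joined), `k`, `K`, `n`, `N`, `p`, `q`,
#'   `odds_ratio`, `rank`; ranked by `q`, then `p`, then term name.
#' @export
ora <- function(query, library, background_n = NULL) {
  if (inherits(query, "gene_set")) query <- query$members
  query <- sort(unique(toupper(as.character(query))))
  eff <- intersect(query, library$universe)
  if (!length(eff)) {
    np_stop("query has no genes in the library universe",
            "netpharm_empty_query_error")
  }
  N <- length(library$universe)
  if (!is.null(background_n)) {
    assert_scalar_number(background_n, "background_n", N, Inf)
    N <- as.integer(background_n)
  }
  n <- length(eff)
  term_names <- names(library$terms)
  rows <- lapply(term_names, function(tn) {
    genes <- library$terms[[tn]]
    ov <- intersect(eff, genes)
    k <- length(ov)
    K <- length(genes)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    list(term = tn, genes = paste(ov, collapse = ";"), k = k, K = K,
         p = min(p, 1), odds_ratio = odds_ratio_2x2(k, K, n, N))
  })
  df <- data.frame(
    term = vapply(rows, `[[`, character(1), "term"),
    genes = vapply(rows, `[[`, character(1), "genes"),
    k = vapply(rows, function(r) as.integer(r$k), integer(1)),
    K = vapply(rows, function(r) as.integer(r$K), integer(1)),
    n = n, N = N,
    p = vapply(rows, `[[`, numeric(1), "p"),
    odds_ratio = vapply(rows, `[[`, numeric(1), "odds_ratio"),
    stringsAsFactors = FALSE
  )
  df$q <- bh_adjust(df$p)
  df <- df[order(df$q, df$p, df$term), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df <- df[c("term", "genes", "k", "K", "n", "N", "p", "q", "odds_ratio", "rank")]
  rownames(df) <- NULL
  class(df) <- c("enrichment_result", "data.frame")
  df
}

#' Select the top terms of an enrichment result
#'
#' @param rows An `enrichment_result` (or compatible data frame).
#' @param by `"q"` (ascending; secondary `p`, tertiary term name) or
#'   `"odds_ratio"` (descending; same secondary keys).
#' @param k Number of terms to return; all rows when `k` exceeds the count.
#' @return The selected rows, re-ranked 1..k.
#' @export
top_terms <- function(rows, by = c("q", "odds_ratio"), k = 5L) {
  by <- match.arg(by)
  assert_scalar_number(k, "k", 1, Inf)
  ord <- if (by == "q") {
    order(rows$q, rows$p, rows$term)
  } else {
    order(-rows$odds_ratio, rows$p, rows$term)
  }
  out <- rows[utils::head(ord, k), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Permutation NES ranking of transcription-factor regulons
#'
#' For each regulon (TF target set) the observed overlap `k` with the query
#' is compared with a null distribution of overlaps obtained from `n_perm`
#' random gene sets of the query's size drawn uniformly from the library
#' universe. `NES = (k - mean_null) / sd_null` (0 when the null has zero
#' spread). Regulons are ranked by NES descending, then by target count,
#' then name.
#'
#' @param query A [gene_set] or character vector (e.g. the core targets).
#' @param tf_library A `gene_set_library` of TF target sets.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @return A data frame of class `tf_rank` with columns `tf`,
#'   `n_targets_hit`, `nes`, `rank`.
#' @export
tf_nes <- function(query, tf_library, n_perm = 1000L, seed = 1L) {
  assert_scalar_number(n_perm, "n_perm", 100, Inf)
  if (inherits(query, "gene_set")) query <- query$members
  query <- sort(unique(toupper(as.character(query))))
  universe <- tf_library$universe
  eff <- intersect(query, universe)
  if (length(universe) < length(query)) {
    np_stop("universe is smaller than the query set", "netpharm_universe_error")
  }
  if (!length(eff)) {
    np_stop("query has no genes in the library universe",
            "netpharm_empty_query_error")
  }
  n <- length(eff)
  terms <- tf_library$terms
  memb <- vapply(terms, function(g) universe %in% g, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L)
  obs <- as.integer(colSums(memb[universe %in% eff, , drop = FALSE]))
  null_hits <- matrix(0L, nrow = as.integer(n_perm), ncol = length(terms))
  with_seed(seed, {
    for (r in seq_len(nrow(null_hits))) {
      idx <- sample.int(length(universe), n)
      null_hits[r, ] <- colSums(memb[idx, , drop = FALSE])
    }
  })
  mu <- colMeans(null_hits)
  sdv <- apply(null_hits, 2L, stats::sd)
  nes <- ifelse(sdv == 0, 0, (obs - mu) / sdv)
  df <- data.frame(tf = names(terms), n_targets_hit = obs, nes = nes,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$nes, -df$n_targets_hit, df$tf), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("tf_rank", "data.frame")
  df
}

#' Write an enrichment result as TSV
#'
#' @param rows An `enrichment_result` or `tf_rank` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(rows, path) {
  utils::write.table(as.data.frame(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
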