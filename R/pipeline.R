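# Config-driven orchestration of the full analysis: target aggregation ->
# Venn intersection -> association expansion -> PPI filtering -> consensus
# hubs -> MCODE modules -> over-representation & TF ranking -> tripartite
# network.  Every stage persists its intermediate under the output
# directory and the report is a pure function of config + seed.

#' Read a pipeline configuration from YAML
#'
#' Relative paths in the file are resolved against its directory.
#'
#' @param path Path to a YAML configuration.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (drug in names(cfg$drug_sources)) {
    cfg$drug_sources[[drug]] <- lapply(cfg$drug_sources[[drug]], fix)
  }
  for (dis in names(cfg$disease_sources)) {
    cfg$disease_sources[[dis]] <- lapply(cfg$disease_sources[[dis]], fix)
  }
  for (f in c("alias_map", "association_network", "ppi", "tf_library")) {
    cfg[[f]] <- fix(cfg[[f]])
  }
  cfg$libraries <- lapply(cfg$libraries, fix)
  cfg
}

pipeline_defaults <- function() {
  list(confidence = 0.7, expansion_k = 20L,
       epc = list(replicates = 1000L, retention_p = 0.5),
       mcode = list(), top_terms_q = 5L, top_terms_or = 3L, top_tf = 10L,
       tf_permutations = 1000L, seed = 1L)
}

fill_defaults <- function(config) {
  utils::modifyList(pipeline_defaults(), config)
}

#' Validate a pipeline configuration
#'
#' Schema, range and file-existence checks; no computation is performed.
#'
#' @param config Configuration list (see [demo_config()] for the shape).
#' @return Character vector of findings; empty when the config is clean.
#' @export
validate_config <- function(config) {
  cfg <- fill_defaults(config)
  findings <- character()
  note <- function(msg) findings <<- c(findings, msg)
  in_range <- function(x, lo, hi) is.numeric(x) && length(x) == 1L &&
    !is.na(x) && x >= lo && x <= hi

  check_file <- function(p, what) {
    if (is.null(p)) note(sprintf("missing required path: %s", what))
    else if (!file.exists(p)) note(sprintf("%s does not exist: %s", what, p))
  }
  if (!length(cfg$drug_sources)) note("no drug_sources configured")
  for (drug in names(cfg$drug_sources)) {
    for (src in names(cfg$drug_sources[[drug]])) {
      check_file(cfg$drug_sources[[drug]][[src]],
                 sprintf("drug_sources.%s.%s", drug, src))
    }
  }
  if (!length(cfg$disease_sources)) note("no disease_sources configured")
  for (dis in names(cfg$disease_sources)) {
    for (src in names(cfg$disease_sources[[dis]])) {
      check_file(cfg$disease_sources[[dis]][[src]],
                 sprintf("disease_sources.%s.%s", dis, src))
    }
  }
  check_file(cfg$association_network, "association_network")
  check_file(cfg$ppi, "ppi")
  for (lib in names(cfg$libraries)) {
    check_file(cfg$libraries[[lib]], sprintf("libraries.%s", lib))
  }
  check_file(cfg$tf_library, "tf_library")
  if (!is.null(cfg$alias_map) && !file.exists(cfg$alias_map)) {
    note(sprintf("alias_map does not exist: %s", cfg$alias_map))
  }
  if (!in_range(cfg$confidence, 0, 1)) note("confidence must be in [0, 1]")
  if (!in_range(cfg$expansion_k, 1, Inf)) note("expansion_k must be >= 1")
  if (!in_range(cfg$epc$replicates, 1, Inf)) note("epc.replicates must be >= 1")
  if (!in_range(cfg$epc$retention_p, 0, 1)) note("epc.retention_p must be in [0, 1]")
  if (!in_range(cfg$top_terms_q, 1, Inf)) note("top_terms_q must be >= 1")
  if (!in_range(cfg$top_terms_or, 1, Inf)) note("top_terms_or must be >= 1")
  if (!in_range(cfg$top_tf, 1, Inf)) note("top_tf must be >= 1")
  if (!in_range(cfg$tf_permutations, 100, Inf)) note("tf_permutations must be >= 100")
  if (!in_range(cfg$seed %||% NA, -2e9, 2e9)) note("seed must be an integer")
  findings
}

#' Run the full network-pharmacology pipeline
#'
#' Executes the stages in analysis order — per-source aggregation, Venn
#' intersection of the drug-target union with the disease sets, association
#' expansion of the intersection, related-set assembly, PPI confidence
#' filtering with isolate removal, four-centrality consensus hub selection,
#' MCODE module mining, over-representation analysis of the related set
#' (top terms by q) and of each module (top terms by odds ratio),
#' permutation-NES TF ranking of the hubs, and tripartite network
#' construction with all-drug common targets. Every intermediate is written
#' under `config$outdir`; the JSON/markdown report is byte-identical across
#' reruns with the same config and seed.
#'
#' @param config Configuration list; see [demo_config()] for a complete
#'   example and [validate_config()] for the checks applied first.
#' @return The pipeline report (list), invisibly.
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  if (length(findings)) {
    np_validation_error(paste0("invalid configuration: ",
                               paste(findings, collapse = "; ")))
  }
  cfg <- fill_defaults(config)
  outdir <- cfg$outdir %||% np_validation_error("config$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      np_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), "netpharm_stage_error")
    })
  }
  alias <- if (!is.null(cfg$alias_map)) read_alias_map(cfg$alias_map) else NULL

  read_entity <- function(sources, label) {
    per_source <- lapply(stats::setNames(nm = names(sources)), function(src) {
      read_gene_list(sources[[src]], alias_map = alias, label = src,
                     source = src)
    })
    aggregate_sources(per_source, label)
  }
  drugs <- stage("targets", lapply(stats::setNames(nm = names(cfg$drug_sources)),
    function(d) read_entity(cfg$drug_sources[[d]], d)))
  diseases <- stage("targets", lapply(stats::setNames(nm = names(cfg$disease_sources)),
    function(d) read_entity(cfg$disease_sources[[d]], d)))
  drug_union <- aggregate_sources(drugs, "drug_union")
  for (gs in c(drugs, diseases)) {
    write_gene_list(gs, file.path(outdir, paste0("targets_", gs$label, ".txt")))
  }

  vres <- stage("venn", venn(c(list(drug_union), unname(diseases))))
  write_venn_summary(vres, file.path(outdir, "venn.json"),
                     file.path(outdir, "venn_regions.tsv"))

  assoc_net <- stage("expand", read_association_tsv(cfg$association_network))
  associated <- stage("expand",
                      expand_related(assoc_net, vres$intersection,
                                     k = cfg$expansion_k))
  related <- combine_related(vres$intersection, associated, "related")
  write_gene_list(related, file.path(outdir, "related_targets.txt"))

  ppi_raw <- stage("ppi", read_edge_tsv(cfg$ppi))
  ppi_net <- drop_isolated(filter_confidence(ppi_raw, cfg$confidence))
  stats_ <- graph_stats(ppi_net)
  write_edge_tsv(ppi_net, file.path(outdir, "ppi_filtered.tsv"))
  write_graphml(ppi_net, file.path(outdir, "ppi_filtered.graphml"))

  hub_res <- stage("hubs", consensus_hubs(
    ppi_net, epc_params(replicates = cfg$epc$replicates,
                        retention_p = cfg$epc$retention_p,
                        seed = stage_seed(cfg$seed, "epc"))))
  write_centrality_tsv(hub_res$table, file.path(outdir, "centrality.tsv"))

  modules <- stage("mcode", mcode(ppi_net, do.call(mcode_params, cfg$mcode)))
  write_modules_tsv(modules, file.path(outdir, "modules.tsv"))

  libs <- lapply(cfg$libraries, read_gmt)
  enr <- stage("ora", lapply(stats::setNames(nm = names(libs)), function(ln) {
    rows <- ora(related, libs[[ln]])
    write_enrichment_tsv(rows, file.path(outdir, paste0("ora_", ln, ".tsv")))
    top_terms(rows, by = "q", k = cfg$top_terms_q)
  }))
  module_lib <- cfg$module_library %||% names(libs)[[1L]]
  module_enr <- stage("ora", lapply(modules, function(mod) {
    rows <- tryCatch(ora(mod$nodes, libs[[module_lib]]),
                     error = function(e) NULL)
    if (is.null(rows)) NULL else top_terms(rows, by = "odds_ratio",
                                           k = cfg$top_terms_or)
  }))

  tf_lib <- read_gmt(cfg$tf_library)
  tf_rank <- stage("tf", tf_nes(hub_res$hubs, tf_lib,
                                n_perm = cfg$tf_permutations,
                                seed = stage_seed(cfg$seed, "tf")))
  write_enrichment_tsv(tf_rank, file.path(outdir, "tf_ranking.tsv"))

  restrict <- function(gs) {
    keep <- intersect(gs$members, related$members)
    gene_set(gs$label, keep, if (length(keep)) gs$provenance[keep])
  }
  tri_drugs <- lapply(drugs, restrict)
  tri_dis <- lapply(diseases, restrict)
  tri <- stage("tripartite", build_tripartite(tri_drugs, tri_dis, related))
  common <- if (length(tri_drugs) >= 2L) {
    common_targets(tri_drugs, restrict_to = related)
  } else {
    gene_set("common_targets", character())
  }
  export_tripartite(tri, file.path(outdir, "tripartite.graphml"), "graphml")
  export_tripartite(tri, file.path(outdir, "tripartite.sif"), "sif")
  export_tripartite(tri, file.path(outdir, "tripartite.json"), "json")

  report <- list(
    seed = cfg$seed,
    parameters = list(
      confidence = cfg$confidence, expansion_k = cfg$expansion_k,
      epc = cfg$epc, top_terms_q = cfg$top_terms_q,
      top_terms_or = cfg$top_terms_or, top_tf = cfg$top_tf,
      tf_permutations = cfg$tf_permutations
    ),
    targets = list(
      per_drug = vapply(drugs, length, integer(1)),
      drug_union = length(drug_union),
      per_disease = vapply(diseases, length, integer(1))
    ),
    venn = as.list(vres$region_counts),
    intersection = vres$intersection$members,
    associated = associated$members,
    related_n = length(related),
    ppi = stats_,
    hubs = hub_res$hubs$members,
    centrality_means = as.list(attr(hub_res$table, "means")),
    modules = lapply(modules, function(m) {
      list(rank = m$rank, seed = m$seed, score = m$score, size = m$size,
           nodes = m$nodes)
    }),
    top_terms = lapply(enr, function(df) as.list(df$term)),
    module_top_terms = lapply(module_enr, function(df) {
      if (is.null(df)) list() else as.list(df$term)
    }),
    tf_top = lapply(seq_len(min(cfg$top_tf, nrow(tf_rank))), function(i) {
      list(tf = tf_rank$tf[i], nes = tf_rank$nes[i],
           n_targets_hit = tf_rank$n_targets_hit[i])
    }),
    tripartite = list(
      n_nodes = nrow(tri$nodes), n_edges = nrow(tri$edges),
      common_targets = common$members
    )
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report_md(report), file.path(outdir, "report.md"))
  invisible(report)
}

render_report_md <- function(rep) {
  c(
    "# Network pharmacology pipeline report",
    "",
    sprintf("- seed: %d", rep$seed),
    sprintf("- drug-target union: %d genes", rep$targets$drug_union),
    sprintf("- intersection targets: %d", length(rep$intersection)),
    sprintf("- associated targets: %d", length(rep$associated)),
    sprintf("- related targets: %d", rep$related_n),
    sprintf("- PPI network: %d nodes, %d edges, %d component(s)",
            rep$ppi$n_nodes, rep$ppi$n_edges, rep$ppi$n_components),
    sprintf("- core targets (consensus hubs): %s",
            paste(rep$hubs, collapse = ", ")),
    sprintf("- modules: %d (%s)", length(rep$modules),
            paste(vapply(rep$modules, function(m)
              sprintf("score %.2f seed %s", m$score, m$seed), character(1)),
              collapse = "; ")),
    sprintf("- top transcription factor: %s",
            if (length(rep$tf_top)) rep$tf_top[[1L]]$tf else "none"),
    sprintf("- tripartite network: %d nodes, %d edges, %d common targets",
            rep$tripartite$n_nodes, rep$tripartite$n_edges,
            length(rep$tripartite$common_targets))
  )
}

#' Generate a self-contained synthetic demo configuration
#'
#' Writes, under `dir`, a complete set of synthetic inputs whose planted
#' structure mirrors the study conditions of a three-drug / two-disease
#' analysis at desk scale: per-source drug target lists (77/77/56 genes with
#' a 12-gene all-drug common core), nested disease sets (all myocardial
#' infarction analog targets contained in the diabetes analog set), a
#' 31-gene drug-disease intersection, an association network with 20
#' planted associates (related set of 51), and a PPI network over the 51
#' related genes with planted cliques of sizes 6/5/4, 3 planted hub genes
#' and 5 low-confidence nodes that drop out at the 0.7 filter. Pathway and
#' TF libraries contain planted terms covering the hub analogs. The ground truth of every generator is written to
#' `fixture_truth.json`.
#'
#' @param dir Directory to create the inputs in.
#' @param seed Master seed; all stage fixtures derive sub-seeds from it.
#' @return The configuration list, with the fixture truth attached as
#'   attribute `"truth"`. A `config.yaml` is written alongside the inputs.
#' @export
demo_config <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  universe <- gen_universe(600)

  sets_fx <- gen_target_sets(
    universe,
    sizes = c(albiglutide_a = 77L, liraglutide_a = 77L, semaglutide_a = 56L,
              T2DM_a = 300L, MI_a = 120L),
    overlaps = list(
      "albiglutide_a&liraglutide_a&semaglutide_a&MI_a" = 12,
      "albiglutide_a&MI_a" = 7,
      "liraglutide_a&MI_a" = 7,
      "semaglutide_a&MI_a" = 5
    ),
    nested = c(MI_a = "T2DM_a"),
    seed = stage_seed(seed, "sets")
  )
  sets <- sets_fx$sets

  split_sources <- function(gs) {
    # two overlapping synthetic source exports per entity
    m <- gs$members
    cut1 <- ceiling(length(m) * 0.6)
    cut0 <- floor(length(m) * 0.4)
    list(dbA = m[seq_len(cut1)], dbB = m[seq.int(cut0 + 1L, length(m))])
  }
  drug_names <- c("albiglutide_a", "liraglutide_a", "semaglutide_a")
  disease_names <- c("T2DM_a", "MI_a")
  drug_sources <- list()
  disease_sources <- list()
  for (nm in c(drug_names, disease_names)) {
    srcs <- split_sources(sets[[nm]])
    paths <- list()
    for (src in names(srcs)) {
      p <- file.path(dir, sprintf("%s_%s.txt", nm, src))
      writeLines(srcs[[src]], p)
      paths[[src]] <- p
    }
    if (nm %in% drug_names) drug_sources[[nm]] <- paths
    else disease_sources[[nm]] <- paths
  }

  inter <- sort(unique(unlist(lapply(drug_names, function(d)
    intersect(sets[[d]]$members, sets$MI_a$members)))))

  assoc_fx <- gen_association(inter, n_associates = 20L, n_background = 40L,
                              seed = stage_seed(seed, "expand"))
  assoc_path <- file.path(dir, "association.tsv")
  el <- igraph::as_edgelist(assoc_fx$graph)
  utils::write.table(
    data.frame(a = el[, 1L], b = el[, 2L],
               w = igraph::E(assoc_fx$graph)$weight),
    assoc_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  related <- sort(c(inter, assoc_fx$truth$planted_associates))
  ppi_nodes <- with_seed(stage_seed(seed, "ppi"), sample(related))
  # 3 hubs: hub MCC dominance over the per-node mean requires roughly
  # N > 7 * n_hubs analyzed nodes (see the methods vignette), and the
  # filtered network keeps ~35-45 of the 51 related genes
  ppi_fx <- gen_ppi(n_background = length(related) - 15L - 3L - 5L,
                    module_sizes = c(6L, 5L, 4L), n_hubs = 3L,
                    background_p = 0.05, n_isolated = 5L,
                    isolated_mode = "low_conf", node_names = ppi_nodes,
                    seed = stage_seed(seed, "ppi"))
  ppi_path <- file.path(dir, "ppi.tsv")
  write_edge_tsv(ppi_fx$graph, ppi_path)

  lib_universe <- sort(unique(c(related, gen_universe(750)[601:750])))
  planted_pathway <- list(PW_PLANTED = sort(c(ppi_fx$truth$planted_hubs,
                                              ppi_fx$truth$planted_modules[[1L]])))
  lib_fx <- gen_library(lib_universe, n_terms = 30L,
                        term_size_range = c(5L, 40L),
                        planted = planted_pathway, name = "pathways",
                        seed = stage_seed(seed, "library"))
  lib_path <- file.path(dir, "pathways.gmt")
  write_gmt(lib_fx$library, lib_path)

  planted_tf <- list(TF_PLANTED = ppi_fx$truth$planted_hubs)
  tf_fx <- gen_library(lib_universe, n_terms = 15L,
                       term_size_range = c(3L, 25L), planted = planted_tf,
                       name = "tf_regulons",
                       seed = stage_seed(seed, "library") + 1L)
  tf_path <- file.path(dir, "tf_regulons.gmt")
  write_gmt(tf_fx$library, tf_path)

  truth <- list(
    seed = seed,
    planted_intersection = inter,
    planted_associates = assoc_fx$truth$planted_associates,
    planted_hubs = sort(ppi_fx$truth$planted_hubs),
    planted_modules = lapply(ppi_fx$truth$planted_modules, sort),
    planted_isolates = sort(ppi_fx$truth$isolated),
    enriched_terms = names(planted_pathway),
    planted_tf = names(planted_tf),
    common_core = sort(Reduce(intersect,
                              lapply(sets[drug_names], `[[`, "members")))
  )
  jsonlite::write_json(truth, file.path(dir, "fixture_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  config <- list(
    seed = as.integer(seed),
    outdir = file.path(dir, "out"),
    drug_sources = drug_sources,
    disease_sources = disease_sources,
    association_network = assoc_path,
    ppi = ppi_path,
    libraries = list(pathways = lib_path),
    tf_library = tf_path,
    confidence = 0.7,
    expansion_k = 20L,
    epc = list(replicates = 1000L, retention_p = 0.5),
    top_terms_q = 5L,
    top_terms_or = 3L,
    top_tf = 10L,
    tf_permutations = 1000L
  )
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  attr(config, "truth") <- truth
  config
}
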