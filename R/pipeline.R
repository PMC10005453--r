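# End-to-end orchestration: screen -> targets -> ppi -> enrich -> network
# (plus dose-response fitting when replicate data are present), with a run
# report mirroring the record-count funnel of the analysis.

#' Pipeline configuration
#'
#' Collects every stage threshold in one place, with the conventional
#' defaults: QED >= 0.3 with Veber on, mean relevance cutoff, STRING high
#' confidence 0.7, key-target criteria degree >= 10 / betweenness >= 0.001 /
#' closeness >= 0.430, top 20 pathways against a 20000-gene background, and
#' max-tie key-component selection.
#'
#' @param input_dir Directory holding a study bundle (see
#'   [write_study_bundle()] for the layout); may be `NULL` when a bundle is
#'   passed to [run_pipeline()] directly.
#' @param out_dir Output directory for artifacts; `NULL` disables writing.
#' @param qed_min,qed_weights Screen settings (see [screen_compounds()]).
#' @param min_probability Target-prediction probability filter.
#' @param relevance_cutoff `"mean"` or numeric (see
#'   [select_potential_targets()]).
#' @param ppi_min_score Edge confidence threshold (see [build_ppi_graph()]).
#' @param min_degree,min_betweenness,min_closeness Key-target criteria.
#' @param top_k,background,ease Enrichment settings (see
#'   [enrich_pathways()]).
#' @param selection `"max-tie"` or an integer (see [rank_by_degree()]).
#' @param seed Recorded in the run report (the pipeline stages themselves
#'   are deterministic).
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = NULL,
                            qed_min = 0.3, qed_weights = "unweighted",
                            min_probability = 0, relevance_cutoff = "mean",
                            ppi_min_score = 0.7, min_degree = 10,
                            min_betweenness = 0.001, min_closeness = 0.430,
                            top_k = 20, background = 20000, ease = FALSE,
                            selection = "max-tie", seed = 1) {
  assert_scalar_number(qed_min, "qed_min", min = 0, max = 1)
  assert_scalar_number(ppi_min_score, "ppi_min_score", min = 0, max = 1)
  assert_count(top_k, "top_k")
  structure(list(
    input_dir = input_dir, out_dir = out_dir,
    qed_min = qed_min, qed_weights = qed_weights,
    min_probability = min_probability, relevance_cutoff = relevance_cutoff,
    ppi_min_score = ppi_min_score, min_degree = min_degree,
    min_betweenness = min_betweenness, min_closeness = min_closeness,
    top_k = top_k, background = background, ease = ease,
    selection = selection, seed = seed
  ), class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", stage,
                  conditionMessage(e)),
          class = "herbnet_stage_error", parent = e)
  })
}

#' Run the full network-pharmacology pipeline
#'
#' Executes screen, target intersection, PPI topology, pathway enrichment
#' and integrated-network ranking in order, fitting dose-response curves
#' when replicate data are present, optionally writing all artifacts, and
#' returning a run report with the per-stage record counts. A rerun with
#' identical inputs and configuration produces an identical report.
#'
#' @param config A [pipeline_config()].
#' @param bundle Optional in-memory `study_bundle`; when `NULL` the bundle
#'   is read from `config$input_dir`.
#'
#' @return A `herbnet_run_report` list: `counts`, `key_components`,
#'   `cutoff_used`, `results` (the stage tibbles), `config`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), bundle = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(bundle)) {
    if (is.null(config$input_dir)) {
      abort("either `bundle` or `config$input_dir` must be supplied",
            class = "herbnet_config_error")
    }
    bundle <- run_stage("load", read_study_bundle(config$input_dir))
  }

  screen <- run_stage("screen",
    screen_compounds(bundle$compounds, qed_min = config$qed_min,
                     weights = config$qed_weights))
  eac_ids <- screen$compound_id[screen$is_eac]

  predicted <- bundle$compound_targets |>
    dplyr::filter(.data$compound_id %in% eac_ids)
  intersected <- run_stage("targets",
    intersect_targets(predicted, bundle$disease_genes,
                      min_probability = config$min_probability))
  potential <- run_stage("targets",
    select_potential_targets(intersected, cutoff = config$relevance_cutoff))

  g <- run_stage("ppi", build_ppi_graph(bundle$ppi_edges,
                                        min_score = config$ppi_min_score))
  in_graph <- intersect(potential$gene_symbol, igraph::V(g)$name)
  g_pot <- run_stage("ppi", igraph::induced_subgraph(g, vids = in_graph))
  cent <- run_stage("ppi", ppi_centralities(g_pot))
  key_targets <- run_stage("ppi",
    select_key_targets(cent, min_degree = config$min_degree,
                       min_betweenness = config$min_betweenness,
                       min_closeness = config$min_closeness))
  if (length(key_targets) == 0L) {
    abort("pipeline stage `ppi` failed: no targets meet the key-target criteria",
          class = "herbnet_stage_error")
  }
  subnet <- run_stage("ppi", induced_subgraph_recompute(g_pot, key_targets))

  enrichment <- run_stage("enrich",
    enrich_pathways(key_targets, bundle$pathways,
                    background = config$background, ease = config$ease))
  top_terms <- run_stage("enrich", top_pathways(enrichment, k = config$top_k))

  ct_key <- predicted |>
    dplyr::filter(.data$probability > config$min_probability,
                  toupper(trimws(.data$gene_symbol)) %in% key_targets) |>
    dplyr::transmute(compound = .data$compound_id,
                     target = toupper(trimws(.data$gene_symbol))) |>
    dplyr::distinct()
  # EAC without any key-target link carry no information; drop them
  linked_eac <- unique(ct_key$compound)
  hc <- bundle$compounds |>
    dplyr::filter(.data$compound_id %in% linked_eac) |>
    tidyr::separate_longer_delim("herbs", delim = ";") |>
    dplyr::transmute(herb = .data$herbs, compound = .data$compound_id) |>
    dplyr::distinct()
  tp <- top_terms |>
    dplyr::select("pathway_id", "hit_genes") |>
    tidyr::unnest_longer("hit_genes") |>
    dplyr::transmute(target = .data$hit_genes, pathway = .data$pathway_id) |>
    dplyr::distinct()
  net <- run_stage("network", build_hctp(hc, ct_key, tp))
  ranking <- run_stage("network",
    rank_by_degree(net, "compound", top = config$selection))
  key_components <- ranking$id[ranking$is_key]

  ic50 <- NULL
  if (!is.null(bundle$dose_response) && nrow(bundle$dose_response) > 0) {
    safe_glance <- function(df) {
      tryCatch(glance(fit_4pl(df)), error = function(e) {
        tibble(ic50 = NA_real_, residual_sse = NA_real_, sigma = NA_real_,
               converged = FALSE, nobs = nrow(df))
      })
    }
    ic50 <- run_stage("fit-ic50",
      bundle$dose_response |>
        dplyr::rename(response = dplyr::any_of(c(response = "aggregation_pct"))) |>
        dplyr::group_by(.data$compound_id) |>
        dplyr::group_modify(~ safe_glance(.x)) |>
        dplyr::ungroup())
  }

  report <- structure(list(
    counts = list(
      collected = nrow(bundle$compounds),
      eac = length(eac_ids),
      intersected = nrow(intersected),
      potential = nrow(potential),
      key_targets = length(key_targets),
      subnetwork_edges = igraph::ecount(subnet$graph),
      pathways_tested = nrow(enrichment),
      pathways_retained = nrow(top_terms),
      hctp_nodes = igraph::vcount(net),
      hctp_edges = igraph::ecount(net),
      key_components = length(key_components)
    ),
    key_components = key_components,
    cutoff_used = attr(potential, "cutoff_used"),
    results = list(screen = screen, potential_targets = potential,
                   centralities = cent, subnetwork = subnet,
                   enrichment = enrichment, top_terms = top_terms,
                   network = net, ranking = ranking, ic50 = ic50),
    config = config,
    seed = config$seed
  ), class = "herbnet_run_report")

  if (!is.null(config$out_dir)) {
    write_run_artifacts(report, config$out_dir)
  }
  report
}

write_run_artifacts <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  readr::write_tsv(res$screen, file.path(dir, "screen.tsv"))
  readr::write_tsv(res$potential_targets, file.path(dir, "potential_targets.tsv"))
  readr::write_tsv(res$centralities, file.path(dir, "centralities.tsv"))
  writeLines(res$subnetwork$centralities$gene_symbol,
             file.path(dir, "key_targets.txt"))
  export_network(res$subnetwork$graph, file.path(dir, "subnetwork.sif"), "sif")
  export_network(res$subnetwork$graph, file.path(dir, "subnetwork.graphml"),
                 "graphml")
  readr::write_tsv(
    dplyr::mutate(res$enrichment,
                  hit_genes = purrr::map_chr(.data$hit_genes, paste,
                                             collapse = ";")),
    file.path(dir, "enrichment.tsv"))
  export_network(res$network, file.path(dir, "hctp.sif"), "sif")
  export_network(res$network, file.path(dir, "hctp.graphml"), "graphml")
  readr::write_tsv(res$ranking, file.path(dir, "ranking.tsv"))
  if (!is.null(res$ic50)) {
    readr::write_tsv(res$ic50, file.path(dir, "ic50.tsv"))
  }
  jsonlite::write_json(
    list(counts = report$counts, key_components = report$key_components,
         cutoff_used = report$cutoff_used, seed = report$seed,
         config = unclass(report$config)[setdiff(names(report$config),
                                                 c("input_dir", "out_dir"))]),
    file.path(dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @export
print.herbnet_run_report <- function(x, ...) {
  cat("Network-pharmacology run\n")
  cts <- x$counts
  cat(sprintf("  compounds %d -> EAC %d -> intersected %d -> potential %d -> key targets %d\n",
              cts$collected, cts$eac, cts$intersected, cts$potential,
              cts$key_targets))
  cat(sprintf("  pathways tested %d, retained %d; H-C-T-P %d nodes / %d edges\n",
              cts$pathways_tested, cts$pathways_retained, cts$hctp_nodes,
              cts$hctp_edges))
  cat(sprintf("  key components (%d): %s\n", cts$key_components,
              paste(x$key_components, collapse = ", ")))
  invisible(x)
}
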