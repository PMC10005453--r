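# Readers and writers for the interchange formats: GMT gene sets, SIF and
# GraphML networks, and the on-disk study bundle layout.

#' Read a GMT gene-set file
#'
#' Standard tab-delimited GMT: set id, description, then member genes.
#'
#' @param path File path.
#' @return A tibble with columns `pathway_id`, `pathway_name`, `genes`
#'   (list column of unique member symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 3L)
  if (length(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", bad[1L]),
          class = "herbnet_parse_error")
  }
  tibble(
    pathway_id = vapply(rows, `[[`, character(1), 1L),
    pathway_name = vapply(rows, `[[`, character(1), 2L),
    genes = purrr::map(rows, ~ unique(.x[-(1:2)]))
  )
}

#' Write a GMT gene-set file
#'
#' @param pathways Tibble with `pathway_id`, `pathway_name`, `genes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  assert_columns(pathways, c("pathway_id", "pathway_name", "genes"), "pathways")
  lines <- purrr::pmap_chr(pathways, function(pathway_id, pathway_name, genes, ...) {
    paste(c(pathway_id, pathway_name, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as SIF or GraphML
#'
#' SIF is the three-column Cytoscape format (`node TAB interaction TAB
#' node`); GraphML carries the `node_class` vertex attribute when present.
#'
#' @param g An igraph object.
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @param interaction Interaction label used in SIF output.
#' @return `path`, invisibly.
#' @export
export_network <- function(g, path, format = c("sif", "graphml"),
                           interaction = "pp") {
  stopifnot(inherits(g, "igraph"))
  format <- match.arg(format)
  if (format == "sif") {
    el <- igraph::as_edgelist(g)
    lines <- if (nrow(el)) paste(el[, 1], interaction, el[, 2], sep = "\t")
             else character()
    # isolated nodes appear as bare node lines, per the SIF convention
    isolated <- igraph::V(g)$name[igraph::degree(g) == 0]
    writeLines(c(lines, isolated), path)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"sif"` or `"graphml"`.
#' @return An igraph object.
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- purrr::keep(parts, ~ length(.x) >= 3L)
    singles <- purrr::keep(parts, ~ length(.x) == 1L)
    el <- if (length(edges)) {
      do.call(rbind, purrr::map(edges, ~ cbind(.x[1], .x[seq(3, length(.x))])))
    } else matrix(character(), ncol = 2)
    nodes <- unique(c(as.vector(el), unlist(singles)))
    g <- igraph::graph_from_data_frame(
      data.frame(from = el[, 1], to = el[, 2]),
      directed = FALSE, vertices = nodes)
    g
  } else {
    igraph::read_graph(path, format = "graphml")
  }
}

#' Write a study bundle to a directory
#'
#' Writes `compounds.tsv`, `compound_targets.tsv`, `disease_genes.tsv`,
#' `ppi_edges.tsv` (STRING-like, `combined_score` on the 0-1000 integer
#' scale), `pathways.gmt`, `dose_response.csv`, and (when ground truth is
#' given) `ground_truth.json`. The serialization is deterministic: the same
#' bundle always produces byte-identical files.
#'
#' @param bundle A `study_bundle` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @param truth Optional `ground_truth` object.
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir, truth = NULL) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(bundle$compounds, file.path(dir, "compounds.tsv"))
  readr::write_tsv(bundle$compound_targets, file.path(dir, "compound_targets.tsv"))
  readr::write_tsv(bundle$disease_genes, file.path(dir, "disease_genes.tsv"))
  ppi <- bundle$ppi_edges
  ppi$combined_score <- as.integer(round(ppi$combined_score * 1000))
  readr::write_tsv(ppi, file.path(dir, "ppi_edges.tsv"))
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  readr::write_csv(bundle$dose_response, file.path(dir, "dose_response.csv"))
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a study bundle from a directory
#'
#' Inverse of [write_study_bundle()]. The STRING-like 0-1000 score scale is
#' rescaled back to 0-1.
#'
#' @param dir Directory written by [write_study_bundle()].
#' @return A `study_bundle`.
#' @export
read_study_bundle <- function(dir) {
  req <- c("compounds.tsv", "compound_targets.tsv", "disease_genes.tsv",
           "ppi_edges.tsv", "pathways.gmt", "dose_response.csv")
  missing <- req[!file.exists(file.path(dir, req))]
  if (length(missing)) {
    abort(sprintf("bundle directory `%s` is missing: %s", dir,
                  paste(missing, collapse = ", ")),
          class = "herbnet_input_error")
  }
  ppi <- readr::read_tsv(file.path(dir, "ppi_edges.tsv"),
                         show_col_types = FALSE)
  if (max(ppi$combined_score) > 1) ppi$combined_score <- ppi$combined_score / 1000
  structure(list(
    compounds = readr::read_tsv(file.path(dir, "compounds.tsv"),
                                show_col_types = FALSE),
    compound_targets = readr::read_tsv(file.path(dir, "compound_targets.tsv"),
                                       show_col_types = FALSE),
    disease_genes = readr::read_tsv(file.path(dir, "disease_genes.tsv"),
                                    show_col_types = FALSE),
    ppi_edges = ppi,
    pathways = read_gmt(file.path(dir, "pathways.gmt")),
    dose_response = readr::read_csv(file.path(dir, "dose_response.csv"),
                                    show_col_types = FALSE)
  ), class = "study_bundle")
}
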