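# PPI graph construction, centrality analysis and key-target selection.
#
# Conventions follow the Cytoscape network analyzer: betweenness is
# shortest-path betweenness with endpoints excluded, normalized by
# (n-1)(n-2)/2 for undirected graphs; closeness is the reciprocal of the mean
# shortest-path distance to *reachable* nodes (component-restricted), 0 for
# isolated nodes.

#' Build a protein-protein interaction graph from a scored edge list
#'
#' Symbols are normalized (uppercased, trimmed), self-loops dropped,
#' duplicate edges in either orientation collapsed keeping the maximum score,
#' and edges below the confidence threshold removed. STRING-style
#' `combined_score` columns on the 0-1000 scale are auto-detected and
#' rescaled to 0-1.
#'
#' @param edges Data frame with columns `protein1`, `protein2`,
#'   `combined_score` (or `score`).
#' @param min_score Minimum confidence kept (default 0.7, STRING "high
#'   confidence").
#'
#' @return An undirected simple [igraph][igraph::graph] with edge attribute
#'   `score`.
#' @export
build_ppi_graph <- function(edges, min_score = 0.7) {
  if (!is.data.frame(edges)) {
    abort("`edges` must be a data frame", class = "herbnet_input_error")
  }
  if (!"combined_score" %in% names(edges) && "score" %in% names(edges)) {
    edges$combined_score <- edges$score
  }
  assert_columns(edges, c("protein1", "protein2", "combined_score"), "edges")
  assert_scalar_number(min_score, "min_score", min = 0, max = 1)

  bad <- which(is.na(edges$protein1) | is.na(edges$protein2) |
                 trimws(edges$protein1) == "" | trimws(edges$protein2) == "" |
                 !is.finite(suppressWarnings(as.numeric(edges$combined_score))))
  if (length(bad)) {
    abort(sprintf("malformed edge row(s): %s",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "herbnet_parse_error")
  }

  score <- as.numeric(edges$combined_score)
  if (length(score) && max(score) > 1) {
    # STRING export dialect: combined_score in 0-1000
    score <- score / 1000
  }

  df <- tibble(
    a = toupper(trimws(edges$protein1)),
    b = toupper(trimws(edges$protein2)),
    score = score
  ) |>
    dplyr::filter(.data$a != .data$b)
  if (nrow(df)) {
    df <- df |>
      dplyr::mutate(
        lo = pmin(.data$a, .data$b),
        hi = pmax(.data$a, .data$b)
      ) |>
      dplyr::summarise(score = max(.data$score), .by = c("lo", "hi")) |>
      dplyr::filter(.data$score >= min_score)
  } else {
    df <- tibble(lo = character(), hi = character(), score = numeric())
  }

  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Degree, betweenness and closeness centralities
#'
#' @param g An undirected simple graph as returned by [build_ppi_graph()].
#'
#' @return A tibble with columns `gene_symbol`, `degree`, `betweenness`,
#'   `closeness`, ordered by descending degree (ties by symbol). Empty graph
#'   gives an empty tibble.
#' @export
ppi_centralities <- function(g) {
  stopifnot(inherits(g, "igraph"))
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(tibble(gene_symbol = character(), degree = integer(),
                  betweenness = numeric(), closeness = numeric()))
  }
  deg <- igraph::degree(g, loops = FALSE)
  btw_raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  btw <- if (n > 2L) btw_raw * 2 / ((n - 1) * (n - 2)) else rep(0, n)

  D <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0L) 0 else 1 / mean(d)
  }, numeric(1))

  tibble(
    gene_symbol = igraph::V(g)$name,
    degree = as.integer(deg),
    betweenness = unname(btw),
    closeness = clo
  ) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene_symbol)
}

#' Select key targets by centrality thresholds
#'
#' Retains genes meeting all three inclusive thresholds, in descending-degree
#' order (ties by symbol).
#'
#' @param centralities Tibble from [ppi_centralities()].
#' @param min_degree,min_betweenness,min_closeness Inclusive thresholds
#'   (defaults 10, 0.001, 0.430).
#'
#' @return Character vector of key-target gene symbols.
#' @export
select_key_targets <- function(centralities, min_degree = 10,
                               min_betweenness = 0.001, min_closeness = 0.430) {
  assert_columns(centralities,
                 c("gene_symbol", "degree", "betweenness", "closeness"),
                 "centralities")
  for (v in c(min_degree, min_betweenness, min_closeness)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      abort("centrality thresholds must be single non-negative numbers",
            class = "herbnet_parameter_error")
    }
  }
  centralities |>
    dplyr::filter(.data$degree >= min_degree,
                  .data$betweenness >= min_betweenness,
                  .data$closeness >= min_closeness) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene_symbol) |>
    dplyr::pull("gene_symbol")
}

#' Induced subgraph with recomputed centralities
#'
#' Restricts the graph to the given nodes (keeping exactly the edges with
#' both endpoints retained) and recomputes all three centralities on the
#' subgraph. This is the step that produces subnetwork-level centrality
#' tables for a selected key-target set.
#'
#' @param g Graph from [build_ppi_graph()].
#' @param keep Character vector of node names, a subset of `V(g)$name`.
#'
#' @return A list with elements `graph` (the induced subgraph) and
#'   `centralities` (tibble from [ppi_centralities()]).
#' @export
induced_subgraph_recompute <- function(g, keep) {
  stopifnot(inherits(g, "igraph"))
  unknown <- setdiff(keep, igraph::V(g)$name)
  if (length(unknown)) {
    abort(sprintf("unknown node(s) in `keep`: %s",
                  paste(head(unknown, 5L), collapse = ", ")),
          class = "herbnet_input_error")
  }
  sub <- igraph::induced_subgraph(g, vids = keep)
  list(graph = sub, centralities = ppi_centralities(sub))
}

#' Edge count implied by a degree sequence
#'
#' Applies the handshake lemma: in any graph the degrees sum to twice the
#' number of edges, so an odd degree sum flags an inconsistent table.
#'
#' @param degrees Numeric vector of node degrees of one closed graph.
#'
#' @return The implied edge count, `sum(degrees) / 2`.
#' @examples
#' edge_count_from_degrees(c(2, 2, 2)) # a triangle
#' @export
edge_count_from_degrees <- function(degrees) {
  if (!is.numeric(degrees) || anyNA(degrees) || any(degrees < 0) ||
      any(degrees != trunc(degrees))) {
    abort("`degrees` must be non-negative integers", class = "herbnet_input_error")
  }
  s <- sum(degrees)
  if (s %% 2 != 0) {
    abort(sprintf("degree sum %d is odd: not a closed graph", s),
          class = "herbnet_consistency_error")
  }
  s / 2
}
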