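# Integrated herb-compound-target-pathway (H-C-T-P) multipartite network and
# degree-based key-component ranking.

.hctp_classes <- c("herb", "compound", "target", "pathway")

#' Build the integrated H-C-T-P network
#'
#' Assembles the multipartite network from the three bipartite edge tables.
#' Node classes are taken from the table/column position (first column of
#' `herb_compound` holds herbs, and so on); an id appearing under two
#' different classes is a structural error. Edges are deduplicated; only
#' adjacent classes (herb-compound, compound-target, target-pathway) can be
#' linked, which the three-table interface enforces by construction.
#'
#' @param herb_compound Data frame, columns `herb`, `compound`.
#' @param compound_target Data frame, columns `compound`, `target` (expected
#'   to be restricted to key targets upstream).
#' @param target_pathway Data frame, columns `target`, `pathway` (expected to
#'   be restricted to the retained top pathways upstream).
#'
#' @return An undirected [igraph][igraph::graph] with vertex attribute
#'   `node_class`.
#' @export
build_hctp <- function(herb_compound, compound_target, target_pathway) {
  assert_columns(herb_compound, c("herb", "compound"), "herb_compound")
  assert_columns(compound_target, c("compound", "target"), "compound_target")
  assert_columns(target_pathway, c("target", "pathway"), "target_pathway")

  edges <- dplyr::bind_rows(
    tibble(from = as.character(herb_compound$herb),
           to = as.character(herb_compound$compound),
           from_class = "herb", to_class = "compound"),
    tibble(from = as.character(compound_target$compound),
           to = as.character(compound_target$target),
           from_class = "compound", to_class = "target"),
    tibble(from = as.character(target_pathway$target),
           to = as.character(target_pathway$pathway),
           from_class = "target", to_class = "pathway")
  )

  if (nrow(edges)) {
    same <- edges$from == edges$to
    if (any(same)) {
      abort(sprintf("edge links a node to itself across classes: %s",
                    edges$from[which(same)[1L]]),
            class = "herbnet_structural_error")
    }
  }

  nodes <- dplyr::bind_rows(
    tibble(id = edges$from, node_class = edges$from_class),
    tibble(id = edges$to, node_class = edges$to_class)
  ) |>
    dplyr::distinct()

  clash <- nodes$id[duplicated(nodes$id)]
  if (length(clash)) {
    abort(sprintf("node(s) assigned to more than one class: %s",
                  paste(unique(clash), collapse = ", ")),
          class = "herbnet_structural_error")
  }

  edges <- dplyr::distinct(edges, .data$from, .data$to)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Rank nodes of one class by degree
#'
#' Degree counts all incident edges regardless of the partner's class (a
#' compound linked to 1 herb and 13 targets has degree 14). `top = "max-tie"`
#' flags the full set of nodes sharing the maximal degree as key components;
#' an integer keeps the top-k rows instead.
#'
#' @param net Network from [build_hctp()].
#' @param node_class One of `"herb"`, `"compound"`, `"target"`, `"pathway"`.
#' @param top `"max-tie"` (default) or a positive integer.
#'
#' @return A tibble (`id`, `degree`, `is_key`) in non-increasing degree order
#'   (ties by id).
#' @export
rank_by_degree <- function(net, node_class = "compound", top = "max-tie") {
  stopifnot(inherits(net, "igraph"))
  if (!is.character(node_class) || length(node_class) != 1L ||
      !node_class %in% .hctp_classes) {
    abort(sprintf("unknown node class `%s`", paste(node_class, collapse = ",")),
          class = "herbnet_parameter_error")
  }
  cls <- igraph::V(net)$node_class
  sel <- which(cls == node_class)
  if (length(sel) == 0L) {
    abort(sprintf("network has no `%s` nodes", node_class),
          class = "herbnet_input_error")
  }
  deg <- igraph::degree(net)[sel]
  out <- tibble(id = igraph::V(net)$name[sel], degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$id)
  if (identical(top, "max-tie")) {
    out$is_key <- out$degree == max(out$degree)
  } else {
    top <- assert_count(top, "top", min = 1L)
    out$is_key <- seq_len(nrow(out)) <= top
  }
  out
}
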