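# Target mapping: intersect predicted compound targets with disease genes and
# retain a relevance-scored potential-target set.

#' Normalize gene symbols
#'
#' Uppercases, trims surrounding whitespace, drops symbols that are empty
#' after trimming (with a warning), and removes duplicates keeping the first
#' occurrence.
#'
#' @param symbols Character vector of gene symbols.
#' @return Character vector of unique normalized symbols.
#' @examples
#' normalize_symbols(c("stat3", "STAT3 ", "Akt1"))
#' @export
normalize_symbols <- function(symbols) {
  if (length(symbols) == 0L) return(character())
  out <- toupper(trimws(as.character(symbols)))
  empty <- is.na(out) | out == ""
  if (any(empty)) {
    warn(sprintf("dropping %d empty gene symbol(s)", sum(empty)))
    out <- out[!empty]
  }
  out[!duplicated(out)]
}

#' Intersect predicted targets with disease genes
#'
#' Keeps the disease genes that are also predicted targets of at least one
#' compound, carrying the disease relevance score. Predictions with
#' `probability <= min_probability` are removed first (the false-positive
#' filter).
#'
#' @param predicted Data frame with columns `compound_id`, `gene_symbol`,
#'   `probability`.
#' @param disease Data frame with columns `gene_symbol`, `relevance_score`.
#' @param min_probability Predictions at or below this probability are
#'   discarded (default 0, i.e. only zero-probability rows are dropped).
#'
#' @return A tibble of the intersected genes (`gene_symbol`,
#'   `relevance_score`), one row per gene, in the disease table's order.
#' @export
intersect_targets <- function(predicted, disease, min_probability = 0) {
  assert_columns(predicted, c("compound_id", "gene_symbol", "probability"), "predicted")
  assert_columns(disease, c("gene_symbol", "relevance_score"), "disease")
  assert_scalar_number(min_probability, "min_probability", min = 0, max = 1)

  kept <- predicted$gene_symbol[predicted$probability > min_probability]
  pred_symbols <- normalize_symbols(kept)

  disease |>
    dplyr::mutate(gene_symbol = toupper(trimws(.data$gene_symbol))) |>
    dplyr::filter(!duplicated(.data$gene_symbol)) |>
    dplyr::filter(.data$gene_symbol %in% pred_symbols) |>
    dplyr::select("gene_symbol", "relevance_score") |>
    as_tibble()
}

#' Select potential targets by relevance-score cutoff
#'
#' Retains genes whose disease relevance score is at or above the cutoff. With
#' `cutoff = "mean"` the cutoff is the arithmetic mean of the input scores
#' (the boundary is inclusive: a gene scoring exactly the cutoff is kept).
#'
#' @param scored Data frame with columns `gene_symbol`, `relevance_score`.
#' @param cutoff `"mean"` (default) or an explicit numeric cutoff.
#'
#' @return A tibble of retained genes with attribute `cutoff_used` recording
#'   the numeric cutoff applied.
#' @export
select_potential_targets <- function(scored, cutoff = "mean") {
  assert_columns(scored, c("gene_symbol", "relevance_score"), "scored")
  if (identical(cutoff, "mean")) {
    if (nrow(scored) == 0L) {
      abort("cannot take a mean cutoff of an empty gene table",
            class = "herbnet_domain_error")
    }
    cutoff_used <- mean(scored$relevance_score)
  } else {
    assert_scalar_number(cutoff, "cutoff", min = 0)
    cutoff_used <- cutoff
  }
  out <- scored |>
    dplyr::filter(.data$relevance_score >= cutoff_used) |>
    as_tibble()
  attr(out, "cutoff_used") <- cutoff_used
  out
}
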