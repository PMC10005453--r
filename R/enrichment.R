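# Pathway over-representation analysis: one-sided hypergeometric tail with
# Benjamini-Hochberg FDR control and top-K ranking.

#' Hypergeometric over-representation p-value
#'
#' Upper tail `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability
#' of drawing at least `k` pathway members when `n` query genes are drawn
#' from a background of `N` genes of which `K` are in the pathway.
#'
#' @param k Overlap count(s).
#' @param K Pathway size in the background.
#' @param n Query size in the background.
#' @param N Background size.
#'
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' hypergeom_p(3, 5, 4, 10) # 55/210
#' @export
hypergeom_p <- function(k, K, n, N) {
  args <- vctrs_recycle(k = k, K = K, n = n, N = N)
  with(args, {
    bad <- k < 0 | K < 0 | n < 0 | N < 1 | K > N | n > N | k > pmin(K, n) |
      k != trunc(k) | K != trunc(K) | n != trunc(n) | N != trunc(N)
    if (any(bad | !is.finite(k + K + n + N))) {
      abort("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) and K, n <= N",
            class = "herbnet_domain_error")
    }
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  })
}

# minimal common-length recycling for scalar-or-vector count arguments
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == len) x else rep_len(x, len)
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order. Input p-values must lie
#' in (0, 1].
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Numeric vector of BH-adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1]", class = "herbnet_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Pathway over-representation analysis
#'
#' Tests each pathway for over-representation of the query genes with the
#' one-sided hypergeometric tail (optionally the EASE variant, which scores
#' `P[X >= k - 1]`), adjusts across tested pathways with Benjamini-Hochberg,
#' and ranks ascending by p-value (ties: descending overlap, then pathway
#' id). Pathways with no overlap are omitted.
#'
#' @param query Character vector of gene symbols (deduplicated and
#'   normalized internally).
#' @param pathways Gene-set collection: a tibble with columns `pathway_id`,
#'   `pathway_name`, `genes` (list column), as returned by [read_gmt()].
#' @param background Either a single count (default 20000, roughly the
#'   protein-coding genome) or a character vector of background symbols; in
#'   the latter case query and sets are restricted to it.
#' @param ease Use the conservative EASE-score variant (default `FALSE`).
#'
#' @return A tibble of class `herbnet_enrichment` with columns `pathway_id`,
#'   `pathway_name`, `k`, `K`, `n`, `N`, `p_value`, `fdr`, `gene_ratio`,
#'   `hit_genes` (list column).
#' @export
enrich_pathways <- function(query, pathways, background = 20000, ease = FALSE) {
  assert_columns(pathways, c("pathway_id", "pathway_name", "genes"), "pathways")
  query <- normalize_symbols(query)
  if (length(query) == 0L) {
    abort("`query` must contain at least one gene symbol",
          class = "herbnet_domain_error")
  }
  sets <- purrr::map(pathways$genes, normalize_symbols)

  if (is.character(background)) {
    bg <- normalize_symbols(background)
    query <- intersect(query, bg)
    sets <- purrr::map(sets, intersect, bg)
    N <- length(bg)
  } else {
    assert_count(background, "background", min = 1L)
    N <- as.integer(background)
    universe_size <- length(unique(c(unlist(sets), query)))
    if (N < universe_size) {
      abort(sprintf("background (%d) smaller than the union of gene sets and query (%d)",
                    N, universe_size),
            class = "herbnet_domain_error")
    }
  }
  n <- length(query)
  if (n == 0L) {
    abort("no query genes left within the background",
          class = "herbnet_domain_error")
  }

  res <- tibble(
    pathway_id = pathways$pathway_id,
    pathway_name = pathways$pathway_name,
    hit_genes = purrr::map(sets, intersect, query),
    K = lengths(sets)
  ) |>
    dplyr::mutate(
      k = lengths(.data$hit_genes),
      n = n,
      N = N
    ) |>
    dplyr::filter(.data$k >= 1L)

  if (nrow(res) == 0L) {
    out <- tibble(pathway_id = character(), pathway_name = character(),
                  k = integer(), K = integer(), n = integer(), N = integer(),
                  p_value = numeric(), fdr = numeric(), gene_ratio = numeric(),
                  hit_genes = list())
    class(out) <- c("herbnet_enrichment", class(out))
    return(out)
  }

  k_eff <- if (isTRUE(ease)) pmax(res$k - 1L, 0L) else res$k
  res <- res |>
    dplyr::mutate(
      p_value = hypergeom_p(k_eff, .data$K, .data$n, .data$N),
      fdr = bh_fdr(.data$p_value),
      gene_ratio = .data$k / .data$n
    ) |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$k), .data$pathway_id) |>
    dplyr::select("pathway_id", "pathway_name", "k", "K", "n", "N",
                  "p_value", "fdr", "gene_ratio", "hit_genes")
  class(res) <- c("herbnet_enrichment", class(res))
  res
}

#' Top-ranked enrichment terms
#'
#' @param results Ranked tibble from [enrich_pathways()].
#' @param k Number of terms to keep (default 20); all if fewer.
#' @return The first `k` rows.
#' @export
top_pathways <- function(results, k = 20) {
  assert_count(k, "k", min = 1L)
  head(results, k)
}

#' Bubble chart of enrichment results
#'
#' Gene ratio against pathway, point size = overlap, colour = p-value: the
#' conventional over-representation display.
#'
#' @param object Tibble from [enrich_pathways()].
#' @param top_n Terms to display (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.herbnet_enrichment <- function(object, top_n = 20, ...) {
  df <- head(object, top_n)
  df$pathway_name <- factor(df$pathway_name, levels = rev(df$pathway_name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_ratio, y = .data$pathway_name,
                                   size = .data$k, colour = .data$p_value)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = "Gene ratio", y = NULL, size = "Count", colour = "p-value") +
    ggplot2::theme_minimal()
}
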