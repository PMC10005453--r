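# Seeded synthetic study generator.
#
# Emulates the complete input bundle of a multi-herb network-pharmacology
# study -- compound descriptor table, compound-target predictions, disease
# gene list with relevance scores, scored PPI edge list, pathway gene sets,
# and replicate dose-response curves -- with planted, recorded ground truth:
# key compounds wired to a shared set of hub targets, hub targets wired to
# the top of the PPI degree distribution, and one pathway enriched for the
# hubs. Every table draws from its own named substream of a single root
# seed, so regenerating any one table leaves the others untouched.

#' Configuration of a synthetic study
#'
#' Defaults mirror a nine-herb prescription study: 119 compounds across 9
#' herbs, a ~400-gene disease list, 110 candidate pathways, 4 planted key
#' compounds sharing 4 planted hub targets, and a 10% + 10% split of
#' compounds planted to fail the QED and Veber screens respectively (so 95
#' of 119 pass by construction).
#'
#' @param n_herbs,n_compounds,n_genes,n_disease_genes,n_pathways Sizes.
#'   `n_genes` is the background gene universe.
#' @param pathway_size_range Two integers, min/max pathway size.
#' @param n_planted_key_compounds,n_planted_hub_targets Planted signal sizes
#'   (>= 0).
#' @param frac_fail_qed,frac_fail_veber Fractions of compounds planted to
#'   fail each screen (disjoint sets, never overlapping the planted key
#'   compounds).
#' @param relevance_dist Lognormal parameters for disease relevance scores,
#'   `list(meanlog=, sdlog=)`; the right skew makes a mean cutoff retain a
#'   minority of genes.
#' @param ppi_model Graph-model parameters,
#'   `list(m=, hub_bias=, core_frac=, core_density=)`: `m` edges per new
#'   node of the preferential-attachment backbone; `hub_bias` the fraction
#'   of each planted hub's extra edges directed at high-relevance disease
#'   genes; `core_frac`/`core_density` define an Erdos-Renyi block over the
#'   top `core_frac` of disease genes by relevance, emulating the dense
#'   disease module that makes degree thresholds meaningful.
#' @param seed Root seed; all randomness flows from it.
#'
#' @return A validated `study_config` list.
#' @export
study_config <- function(n_herbs = 9, n_compounds = 119, n_genes = 2000,
                         n_disease_genes = 400, n_pathways = 110,
                         pathway_size_range = c(10, 80),
                         n_planted_key_compounds = 4,
                         n_planted_hub_targets = 4,
                         frac_fail_qed = 0.1, frac_fail_veber = 0.1,
                         relevance_dist = list(meanlog = 0.5, sdlog = 1),
                         ppi_model = list(m = 2, hub_bias = 0.6,
                                          core_frac = 0.2, core_density = 0.3),
                         seed = 1) {
  cfg <- list(
    n_herbs = assert_count(n_herbs, "n_herbs"),
    n_compounds = assert_count(n_compounds, "n_compounds"),
    n_genes = assert_count(n_genes, "n_genes"),
    n_disease_genes = assert_count(n_disease_genes, "n_disease_genes"),
    n_pathways = assert_count(n_pathways, "n_pathways"),
    pathway_size_range = pathway_size_range,
    n_planted_key_compounds = assert_count(n_planted_key_compounds,
                                           "n_planted_key_compounds", min = 0L),
    n_planted_hub_targets = assert_count(n_planted_hub_targets,
                                         "n_planted_hub_targets", min = 0L),
    frac_fail_qed = assert_fraction(frac_fail_qed, "frac_fail_qed"),
    frac_fail_veber = assert_fraction(frac_fail_veber, "frac_fail_veber"),
    relevance_dist = relevance_dist,
    ppi_model = ppi_model,
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (length(pathway_size_range) != 2L ||
      any(pathway_size_range < 1) ||
      pathway_size_range[1] > pathway_size_range[2] ||
      pathway_size_range[2] > cfg$n_genes) {
    abort("`pathway_size_range` must be (min, max) with 1 <= min <= max <= n_genes",
          class = "herbnet_config_error")
  }
  cfg$pathway_size_range <- as.integer(pathway_size_range)
  if (cfg$n_disease_genes > cfg$n_genes) {
    abort("`n_disease_genes` cannot exceed `n_genes`",
          class = "herbnet_config_error")
  }
  if (cfg$n_herbs > cfg$n_compounds) {
    abort("`n_herbs` cannot exceed `n_compounds`",
          class = "herbnet_config_error")
  }
  if (cfg$n_planted_hub_targets > cfg$n_disease_genes) {
    abort("`n_planted_hub_targets` cannot exceed `n_disease_genes`",
          class = "herbnet_config_error")
  }
  n_fail <- round(cfg$frac_fail_qed * cfg$n_compounds) +
    round(cfg$frac_fail_veber * cfg$n_compounds)
  if (cfg$n_planted_key_compounds + n_fail > cfg$n_compounds) {
    abort("`n_planted_key_compounds` plus planted screen failures exceed `n_compounds`",
          class = "herbnet_config_error")
  }
  if (!is.list(relevance_dist) ||
      !all(c("meanlog", "sdlog") %in% names(relevance_dist))) {
    abort("`relevance_dist` must be list(meanlog=, sdlog=)",
          class = "herbnet_config_error")
  }
  if (!is.list(ppi_model) ||
      !all(c("m", "hub_bias", "core_frac", "core_density") %in% names(ppi_model))) {
    abort("`ppi_model` must be list(m=, hub_bias=, core_frac=, core_density=)",
          class = "herbnet_config_error")
  }
  structure(cfg, class = "study_config")
}

# descriptor sampling boxes; the in-range box always passes both screens,
# the veber box fails only ROTB, the qed box fails only QED (verified
# against the ADS parameter table: worst in-range corner QED 0.355, veber
# box worst 0.481, qed box best 0.243)
sample_descriptors <- function(n, box = c("pass", "fail_qed", "fail_veber")) {
  box <- match.arg(box)
  switch(box,
    pass = tibble(
      MW = runif(n, 220, 420), ALOGP = runif(n, 0.5, 4),
      HBA = sample(2:8, n, replace = TRUE), HBD = sample(0:4, n, replace = TRUE),
      PSA = runif(n, 40, 120), ROTB = sample(0:8, n, replace = TRUE),
      AROM = sample(1:3, n, replace = TRUE),
      ALERT = sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2))
    ),
    fail_qed = tibble(
      MW = runif(n, 700, 900), ALOGP = runif(n, 6.5, 8),
      HBA = sample(2:8, n, replace = TRUE), HBD = sample(0:4, n, replace = TRUE),
      PSA = runif(n, 40, 120), ROTB = sample(0:8, n, replace = TRUE),
      AROM = sample(1:3, n, replace = TRUE),
      ALERT = sample(4:6, n, replace = TRUE)
    ),
    fail_veber = tibble(
      MW = runif(n, 220, 350), ALOGP = runif(n, 0.5, 3),
      HBA = sample(2:6, n, replace = TRUE), HBD = sample(0:2, n, replace = TRUE),
      PSA = runif(n, 40, 100), ROTB = sample(11:14, n, replace = TRUE),
      AROM = sample(1:2, n, replace = TRUE),
      ALERT = rep(0L, n)
    )
  )
}

#' Generate a complete synthetic study bundle
#'
#' @param config A [study_config()].
#'
#' @return A list with elements `bundle` (class `study_bundle`: tibbles
#'   `compounds`, `compound_targets`, `disease_genes`, `ppi_edges`,
#'   `pathways`, `dose_response`) and `truth` (class `ground_truth`: the
#'   planted compound ids, hub symbols, enriched pathway id, and true
#'   dose-response parameters).
#' @export
generate_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) config <- do.call(study_config, config)
  seed <- config$seed

  genes <- sprintf("G%05d", seq_len(config$n_genes))
  herbs <- sprintf("HERB%02d", seq_len(config$n_herbs))
  compound_ids <- sprintf("CPD%04d", seq_len(config$n_compounds))

  # --- planted assignments -------------------------------------------------
  n_fq <- round(config$frac_fail_qed * config$n_compounds)
  n_fv <- round(config$frac_fail_veber * config$n_compounds)
  plant <- with_substream(seed, "plant", {
    ord <- sample(compound_ids)
    list(
      key = if (config$n_planted_key_compounds > 0)
        sort(ord[seq_len(config$n_planted_key_compounds)]) else character(),
      fail_qed = if (n_fq > 0)
        sort(ord[config$n_planted_key_compounds + seq_len(n_fq)]) else character(),
      fail_veber = if (n_fv > 0)
        sort(ord[config$n_planted_key_compounds + n_fq + seq_len(n_fv)])
      else character()
    )
  })

  # --- compounds: herb provenance + descriptors ----------------------------
  herb_of <- with_substream(seed, "herbs", {
    h <- c(herbs, sample(herbs, config$n_compounds - config$n_herbs,
                         replace = TRUE))
    sample(h)  # shuffle so the guaranteed-coverage block is not positional
  })
  descriptors <- with_substream(seed, "descriptors", {
    d <- sample_descriptors(config$n_compounds, "pass")
    if (length(plant$fail_qed)) {
      d[match(plant$fail_qed, compound_ids), ] <-
        sample_descriptors(length(plant$fail_qed), "fail_qed")
    }
    if (length(plant$fail_veber)) {
      d[match(plant$fail_veber, compound_ids), ] <-
        sample_descriptors(length(plant$fail_veber), "fail_veber")
    }
    d
  })
  compounds <- dplyr::bind_cols(
    tibble(compound_id = compound_ids,
           name = paste0("compound_", seq_len(config$n_compounds)),
           herbs = herb_of,
           smiles = NA_character_),
    descriptors
  )

  # --- disease genes with lognormal relevance; hubs forced high ------------
  disease <- with_substream(seed, "disease", {
    syms <- sort(sample(genes, config$n_disease_genes))
    rel <- rlnorm(config$n_disease_genes,
                  meanlog = config$relevance_dist$meanlog,
                  sdlog = config$relevance_dist$sdlog)
    hubs <- if (config$n_planted_hub_targets > 0)
      sort(sample(syms, config$n_planted_hub_targets)) else character()
    q90 <- quantile(rel, 0.9, names = FALSE)
    rel[syms %in% hubs] <- q90 * 1.5
    # shared key-target set: every planted key compound links to exactly
    # these genes, so the planted compounds form the max-degree tie class
    n_shared <- min(10L, config$n_disease_genes - length(hubs))
    shared <- if (n_shared > 0)
      sort(sample(setdiff(syms, hubs), n_shared)) else character()
    rel[syms %in% shared] <- q90 * 1.3
    list(tbl = tibble(gene_symbol = syms, relevance_score = rel),
         hubs = hubs, shared = shared)
  })
  hubs <- disease$hubs
  shared <- disease$shared

  # --- PPI: preferential attachment + hub over-wiring ----------------------
  ppi_edges <- with_substream(seed, "ppi", {
    g <- igraph::sample_pa(config$n_genes, power = 1, m = config$ppi_model$m,
                           directed = FALSE)
    igraph::V(g)$name <- genes
    el <- igraph::as_edgelist(g)
    base <- tibble(protein1 = el[, 1], protein2 = el[, 2],
                   combined_score = runif(nrow(el), 0.4, 0.999))
    # dense disease-module block among the top-relevance disease genes
    rel_tbl <- disease$tbl
    core_n <- round(config$ppi_model$core_frac * config$n_disease_genes)
    core <- NULL
    if (core_n >= 2) {
      core_genes <- rel_tbl$gene_symbol[order(-rel_tbl$relevance_score)][seq_len(core_n)]
      pairs <- utils::combn(sort(core_genes), 2)
      keep <- runif(ncol(pairs)) < config$ppi_model$core_density
      if (any(keep)) {
        core <- tibble(protein1 = pairs[1, keep], protein2 = pairs[2, keep],
                       combined_score = runif(sum(keep), 0.7, 0.999))
      }
    }
    backbone <- dplyr::bind_rows(base, core)
    deg_backbone <- table(c(backbone$protein1, backbone$protein2))
    max_base <- max(deg_backbone)
    # each hub gets enough extra edges to outrank every non-hub, biased
    # toward high-relevance disease genes so hubs stay central in the
    # potential-target subnetwork
    extra <- purrr::map_dfr(hubs, function(h) {
      k_h <- min(config$n_genes - 1L,
                 max_base + length(hubs) + 6L)
      high <- rel_tbl$gene_symbol[rel_tbl$relevance_score >=
                                    median(rel_tbl$relevance_score)]
      high <- setdiff(high, h)
      n_high <- min(length(high), round(config$ppi_model$hub_bias * k_h))
      pick_high <- sample(high, n_high)
      rest_pool <- setdiff(genes, c(h, pick_high))
      pick_rest <- sample(rest_pool, k_h - n_high)
      tibble(protein1 = h, protein2 = c(pick_high, pick_rest),
             combined_score = runif(k_h, 0.75, 0.999))
    })
    dplyr::bind_rows(backbone, extra) |>
      dplyr::mutate(lo = pmin(.data$protein1, .data$protein2),
                    hi = pmax(.data$protein1, .data$protein2)) |>
      dplyr::summarise(combined_score = max(.data$combined_score),
                       .by = c("lo", "hi")) |>
      dplyr::transmute(protein1 = .data$lo, protein2 = .data$hi,
                       combined_score = .data$combined_score) |>
      dplyr::arrange(.data$protein1, .data$protein2)
  })

  # --- compound-target predictions ----------------------------------------
  compound_targets <- with_substream(seed, "targets", {
    non_disease <- setdiff(genes, disease$tbl$gene_symbol)
    purrr::map_dfr(compound_ids, function(cid) {
      if (cid %in% plant$key) {
        tg <- c(hubs, shared)
        if (length(tg) == 0L) tg <- sample(disease$tbl$gene_symbol, 5L)
        tibble(compound_id = cid, gene_symbol = tg,
               probability = runif(length(tg), 0.6, 0.95))
      } else {
        n_t <- sample(3:6, 1L)
        n_d <- sum(runif(n_t) < 0.7)
        tg <- unique(c(
          sample(disease$tbl$gene_symbol, min(n_d, config$n_disease_genes)),
          if (n_t - n_d > 0 && length(non_disease))
            sample(non_disease, min(n_t - n_d, length(non_disease)))
        ))
        tibble(compound_id = cid, gene_symbol = tg,
               probability = runif(length(tg), 0.05, 0.95))
      }
    })
  })

  # --- pathways: one planted enriched set + random sets --------------------
  pathways <- with_substream(seed, "pathways", {
    ids <- sprintf("PATH%04d", seq_len(config$n_pathways))
    sizes <- sample(seq(config$pathway_size_range[1],
                        config$pathway_size_range[2]),
                    config$n_pathways, replace = TRUE)
    planted_members <- unique(c(hubs, shared))
    planted_size <- min(config$n_genes,
                        max(sizes[1], length(planted_members)))
    fill <- setdiff(genes, planted_members)
    members1 <- c(planted_members,
                  sample(fill, planted_size - length(planted_members)))
    sets <- c(list(members1),
              purrr::map(sizes[-1], ~ sample(genes, .x)))
    tibble(pathway_id = ids,
           pathway_name = paste0("pathway_", seq_along(ids)),
           genes = sets)
  })

  # --- dose-response for the planted key compounds -------------------------
  conc_grid <- 10^seq(0, 2, length.out = 6)
  dr <- with_substream(seed, "dose_params", {
    n <- length(plant$key)
    tibble(
      compound_id = plant$key,
      bottom = rep(0, n),
      top = rep(83, n),
      ic50 = exp(runif(n, log(15), log(60))),
      slope = runif(n, 1.2, 2)
    )
  })
  dose_response <- purrr::map_dfr(seq_len(nrow(dr)), function(i) {
    generate_dose_response(
      params = c(bottom = dr$bottom[i], top = dr$top[i],
                 ic50 = dr$ic50[i], slope = dr$slope[i]),
      concentrations = conc_grid, n_reps = 4, noise_sd = 2.4,
      seed = substream_seed(seed, paste0("dose_", dr$compound_id[i]))
    ) |>
      dplyr::mutate(compound_id = dr$compound_id[i], .before = 1)
  })

  bundle <- structure(list(
    compounds = compounds,
    compound_targets = compound_targets,
    disease_genes = disease$tbl,
    ppi_edges = ppi_edges,
    pathways = pathways,
    dose_response = dose_response
  ), class = "study_bundle")

  truth <- structure(list(
    planted_key_compound_ids = plant$key,
    planted_fail_qed_ids = plant$fail_qed,
    planted_fail_veber_ids = plant$fail_veber,
    planted_hub_target_symbols = hubs,
    planted_shared_target_symbols = shared,
    planted_enriched_pathway_id = pathways$pathway_id[1],
    true_ic50 = setNames(dr$ic50, dr$compound_id),
    true_hill_params = dr
  ), class = "ground_truth")

  list(bundle = bundle, truth = truth)
}

#' Simulate replicate dose-response measurements from a 4PL curve
#'
#' Evaluates the four-parameter logistic at each concentration, adds
#' Gaussian noise, and truncates to the aggregation-percentage range
#' \[0, 100\].
#'
#' @param params Named vector or list with `bottom`, `top` (%), `ic50`
#'   (concentration units, > 0), `slope`.
#' @param concentrations Positive concentration grid.
#' @param n_reps Replicates per concentration (default 4).
#' @param noise_sd Gaussian noise SD in percentage points (default 2.4, a
#'   typical vehicle-control SD).
#' @param seed Integer seed.
#'
#' @return A tibble (`concentration`, `replicate`, `response`).
#' @export
generate_dose_response <- function(params, concentrations, n_reps = 4,
                                   noise_sd = 2.4, seed = 1) {
  params <- as.list(params)
  for (nm in c("bottom", "top", "ic50", "slope")) {
    if (is.null(params[[nm]]) || !is.finite(params[[nm]])) {
      abort(sprintf("`params` must supply finite `%s`", nm),
            class = "herbnet_domain_error")
    }
  }
  if (params$ic50 <= 0) {
    abort("`ic50` must be positive", class = "herbnet_domain_error")
  }
  if (!is.numeric(concentrations) || length(concentrations) == 0L ||
      any(concentrations <= 0)) {
    abort("`concentrations` must be positive", class = "herbnet_domain_error")
  }
  n_reps <- assert_count(n_reps, "n_reps")
  assert_scalar_number(noise_sd, "noise_sd", min = 0)

  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(concentration = concentrations,
                               replicate = seq_len(n_reps))
    mu <- four_pl(grid$concentration, params$bottom, params$top,
                  params$ic50, params$slope)
    grid$response <- pmin(pmax(mu + rnorm(nrow(grid), 0, noise_sd), 0), 100)
    grid
  })
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Synthetic study bundle\n")
  cat(sprintf("  %d compounds, %d target predictions, %d disease genes\n",
              nrow(x$compounds), nrow(x$compound_targets), nrow(x$disease_genes)))
  cat(sprintf("  %d PPI edges, %d pathways, %d dose-response rows\n",
              nrow(x$ppi_edges), nrow(x$pathways), nrow(x$dose_response)))
  invisible(x)
}
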