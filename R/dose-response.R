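# Four-parameter logistic (4PL) dose-response analysis of platelet
# aggregation, plus inhibition summaries and the vehicle-control comparison.
#
# Model: y(c) = bottom + (top - bottom) / (1 + (c / ic50)^slope).
# With slope > 0 the response falls from `top` (no drug) to `bottom` (full
# inhibition) and equals the midpoint at c = ic50.

four_pl <- function(conc, bottom, top, ic50, slope) {
  bottom + (top - bottom) / (1 + (conc / ic50)^slope)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit on the log-concentration scale via
#' Levenberg-Marquardt, with a deterministic initialization (bottom/top from
#' the per-concentration mean extrema, IC50 from the concentrations
#' bracketing the half-maximal response, slope 1) and box constraints
#' (`bottom >= 0`, `top <= 110`, `slope` in [0.1, 10]).
#'
#' @param data Data frame with numeric columns `concentration` (> 0, in the
#'   assay's concentration unit, conventionally uM) and `response`
#'   (aggregation %, one row per replicate measurement). At least 4 distinct
#'   concentrations are required.
#' @param top_max Upper bound for the `top` plateau (default 110%).
#'
#' @return An object of class `fit_4pl` with elements `coefficients`
#'   (`bottom`, `top`, `ic50`, `slope`), `residual_sse`, `converged`, `data`,
#'   and the underlying `fit`. Supports [coef()], [predict()], [tidy()],
#'   [glance()] and [autoplot()].
#' @export
fit_4pl <- function(data, top_max = 110) {
  assert_columns(data, c("concentration", "response"), "data")
  conc <- data$concentration
  y <- data$response
  if (anyNA(conc) || anyNA(y) || any(!is.finite(conc)) || any(!is.finite(y))) {
    abort("dose-response data must be finite", class = "herbnet_domain_error")
  }
  if (any(conc <= 0)) {
    abort("concentrations must be positive", class = "herbnet_domain_error")
  }
  if (length(unique(conc)) < 4L) {
    abort("need at least 4 distinct concentrations to fit a 4PL",
          class = "herbnet_fit_error")
  }

  cgrid <- sort(unique(conc))
  means <- vapply(cgrid, function(cc) mean(y[conc == cc]), numeric(1))
  rng <- max(means) - min(means)
  if (rng < 1e-8) {
    abort("flat dose-response (no dynamic range): IC50 is not identifiable",
          class = "herbnet_fit_error")
  }

  bottom0 <- max(min(means), 0)
  top0 <- min(max(means), top_max)
  mid <- (min(means) + max(means)) / 2
  # first concentration whose mean crosses the midpoint, interpolated
  # geometrically with its lower neighbour
  below <- which(means <= mid)
  ic50_0 <- if (length(below) == 0L || min(below) == 1L) {
    exp(mean(log(range(cgrid))))
  } else {
    i <- min(below)
    sqrt(cgrid[i] * cgrid[i - 1L])
  }

  df <- data.frame(conc = conc, y = y)
  gm <- exp(mean(log(range(conc))))
  # deterministic ladder of starting points: the data-driven heuristic
  # first, then progressively more generic fallbacks (box-constrained LM can
  # reject an otherwise fine start on perfect-fit data)
  starts <- list(
    list(bottom = bottom0, top = top0, lic50 = log(ic50_0), slope = 1),
    list(bottom = bottom0, top = top0, lic50 = log(ic50_0), slope = 1.5),
    list(bottom = max(bottom0 - 0.05 * rng, 0),
         top = min(top0 + 0.05 * rng, top_max), lic50 = log(gm), slope = 1),
    list(bottom = 0, top = top0, lic50 = log(ic50_0), slope = 2)
  )
  fit <- NULL
  last_err <- "no attempt"
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(slope * (log(conc) - lic50))),
        data = df,
        start = st,
        lower = c(bottom = 0, top = 0, lic50 = log(min(conc)) - log(1e4),
                  slope = 0.1),
        upper = c(bottom = top_max, top = top_max,
                  lic50 = log(max(conc)) + log(1e4), slope = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # box-constrained LM occasionally fails on boundary solutions (e.g. a
    # perfect fit with bottom exactly 0); retry unconstrained and accept the
    # solution only if it respects the box
    for (st in starts) {
      cand <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + exp(slope * (log(conc) - lic50))),
          data = df, start = st,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) {
          last_err <<- conditionMessage(e)
          NULL
        }
      )
      if (!is.null(cand)) {
        cf <- coef(cand)
        in_box <- cf[["bottom"]] >= -1e-6 && cf[["top"]] <= top_max + 1e-6 &&
          cf[["slope"]] >= 0.1 - 1e-6 && cf[["slope"]] <= 10 + 1e-6
        if (in_box) {
          fit <- cand
          break
        }
        last_err <- "unconstrained solution violates parameter bounds"
      }
    }
  }
  if (is.null(fit)) {
    abort(sprintf("4PL fit failed: %s", last_err), class = "herbnet_fit_error")
  }

  cf <- coef(fit)
  cf[["bottom"]] <- max(cf[["bottom"]], 0)
  out <- list(
    coefficients = c(bottom = unname(cf[["bottom"]]),
                     top = unname(cf[["top"]]),
                     ic50 = exp(unname(cf[["lic50"]])),
                     slope = unname(cf[["slope"]])),
    residual_sse = sum(resid(fit)^2),
    converged = isTRUE(fit$convInfo$isConv),
    n = length(y),
    data = as_tibble(data[c("concentration", "response")]),
    fit = fit
  )
  class(out) <- "fit_4pl"
  out
}

#' @export
coef.fit_4pl <- function(object, ...) object$coefficients

#' @export
predict.fit_4pl <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration else newdata$concentration
  cf <- object$coefficients
  four_pl(conc, cf[["bottom"]], cf[["top"]], cf[["ic50"]], cf[["slope"]])
}

#' @export
print.fit_4pl <- function(x, ...) {
  cf <- x$coefficients
  cat("Four-parameter logistic fit\n")
  cat(sprintf("  bottom %.2f%%  top %.2f%%  IC50 %.4g  slope %.3f\n",
              cf[["bottom"]], cf[["top"]], cf[["ic50"]], cf[["slope"]]))
  cat(sprintf("  residual SSE %.4g on %d observations; converged: %s\n",
              x$residual_sse, x$n, x$converged))
  invisible(x)
}

#' Tidy a 4PL fit
#'
#' @param x A `fit_4pl` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.fit_4pl <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  se <- sm[, "Std. Error"]
  # delta method for ic50 = exp(lic50)
  est <- x$coefficients
  se_out <- c(bottom = unname(se[["bottom"]]), top = unname(se[["top"]]),
              ic50 = unname(se[["lic50"]]) * est[["ic50"]],
              slope = unname(se[["slope"]]))
  tibble(term = names(est), estimate = unname(est), std.error = unname(se_out))
}

#' Glance at a 4PL fit
#'
#' @param x A `fit_4pl` object.
#' @param ... Unused.
#' @return A one-row tibble (`ic50`, `residual_sse`, `sigma`, `converged`,
#'   `nobs`).
#' @export
glance.fit_4pl <- function(x, ...) {
  tibble(ic50 = x$coefficients[["ic50"]],
         residual_sse = x$residual_sse,
         sigma = summary(x$fit)$sigma,
         converged = x$converged,
         nobs = x$n)
}

#' Plot a 4PL fit
#'
#' Replicate points with the fitted curve on a log-concentration axis.
#'
#' @param object A `fit_4pl` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fit_4pl <- function(object, ...) {
  rng <- range(object$data$concentration)
  grid <- tibble(concentration = exp(seq(log(rng[1]), log(rng[2]),
                                         length.out = 200)))
  grid$response <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration", y = "Aggregation (%)") +
    ggplot2::theme_minimal()
}

#' Percent inhibition from condition means
#'
#' `(agonist - treated) / (agonist - baseline) * 100`: 0% when treatment
#' leaves the agonist response unchanged, 100% when it restores the
#' unstimulated baseline. Values outside [0, 100] (treatment apparently
#' worse than vehicle, or below baseline) are clipped with a warning.
#'
#' @param agonist_mean Agonist-induced vehicle-control mean.
#' @param treated_mean Treated-condition mean.
#' @param baseline_mean Unstimulated baseline mean.
#' @return Percent inhibition in [0, 100].
#' @export
percent_inhibition <- function(agonist_mean, treated_mean, baseline_mean) {
  if (any(!is.finite(c(agonist_mean, treated_mean, baseline_mean)))) {
    abort("condition means must be finite", class = "herbnet_domain_error")
  }
  if (any(agonist_mean <= baseline_mean)) {
    abort("agonist mean must exceed the baseline mean",
          class = "herbnet_domain_error")
  }
  x <- (agonist_mean - treated_mean) / (agonist_mean - baseline_mean) * 100
  if (any(x < 0 | x > 100)) {
    warn("percent inhibition outside [0, 100]; clipping")
    x <- pmin(pmax(x, 0), 100)
  }
  x
}

#' Compare treated replicates with the vehicle control
#'
#' Two-sided Welch two-sample test by default (rank-based Wilcoxon
#' available). Identical degenerate samples (zero variance in both groups
#' with equal means) return the maximal p-value 1. Stars follow the printed
#' thresholds: `**` for p < 0.001, `*` for p < 0.05.
#'
#' @param treated,control Numeric replicate vectors (>= 2 each).
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @return A one-row tibble (`p_value`, `stars`, `method`).
#' @export
compare_to_control <- function(treated, control, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  if (length(treated) < 2L || length(control) < 2L) {
    abort("need at least 2 replicates per group", class = "herbnet_input_error")
  }
  p <- if (stats::sd(treated) == 0 && stats::sd(control) == 0) {
    if (mean(treated) == mean(control)) 1 else 0
  } else if (method == "welch") {
    t.test(treated, control, var.equal = FALSE)$p.value
  } else {
    suppressWarnings(wilcox.test(treated, control, exact = FALSE)$p.value)
  }
  tibble(
    p_value = p,
    stars = if (p < 0.001) "**" else if (p < 0.05) "*" else "",
    method = method
  )
}

#' Inhibition summary for a measured-condition table
#'
#' Summarizes a TxB2-style replicate table: per-condition mean and SD,
#' percent inhibition of every treated condition relative to the agonist
#' control and baseline, and the p-value of the treated-versus-agonist
#' comparison.
#'
#' @param data Data frame with columns `condition`, `value` (one row per
#'   replicate).
#' @param agonist Name of the agonist-induced vehicle-control condition.
#' @param baseline Name of the unstimulated baseline condition.
#' @param method Passed to [compare_to_control()].
#'
#' @return A tibble with one row per treated condition: `condition`, `mean`,
#'   `sd`, `n`, `percent_inhibition`, `p_value`, `stars`.
#' @export
summarize_inhibition <- function(data, agonist, baseline,
                                 method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  assert_columns(data, c("condition", "value"), "data")
  conds <- unique(data$condition)
  if (!agonist %in% conds || !baseline %in% conds) {
    abort("`agonist` and `baseline` conditions must be present in `data`",
          class = "herbnet_input_error")
  }
  ago <- data$value[data$condition == agonist]
  base <- data$value[data$condition == baseline]
  treated <- setdiff(conds, c(agonist, baseline))
  purrr::map_dfr(treated, function(cond) {
    v <- data$value[data$condition == cond]
    cmp <- compare_to_control(v, ago, method = method)
    tibble(
      condition = cond,
      mean = mean(v),
      sd = stats::sd(v),
      n = length(v),
      percent_inhibition = percent_inhibition(mean(ago), mean(v), mean(base)),
      p_value = cmp$p_value,
      stars = cmp$stars
    )
  })
}
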