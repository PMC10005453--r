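# QED drug-likeness and Veber oral-bioavailability screening.
#
# The quantitative estimate of drug-likeness (QED) maps eight physicochemical
# descriptors through asymmetric double-sigmoid (ADS) desirability functions
# and combines them as a (weighted) geometric mean. The ADS parameters below
# are the published fitted constants for the eight descriptors (a, b, c, d,
# e, f and the normalizing maximum DMAX); they are versioned data, never
# refit at run time.

.qed_properties <- c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERT")

.qed_ads_params <- matrix(
  c(
    # a            b            c            d            e           f           dmax
    2.817065973,  392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561,  # MW
    3.172690585,  137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604,  # ALOGP
    2.948620388,  160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046,  # HBA
    1.618662227, 1010.051101,  0.985094388, 1e-09,       0.713820843, 0.920922555, 258.1632616,  # HBD
    1.876861559,  125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167,  # PSA
    0.01,         272.4121427, 2.55837997,  1.565547684, 1.271567166, 2.758063707, 105.4420403,  # ROTB
    3.21778897,   957.7374108, 2.274627939, 1e-09,       1.317690384, 0.375760881, 312.337261,   # AROM
    0.01,        1199.094025, -0.09002883,  1e-09,       0.185904477, 0.875193782, 417.725314    # ALERT
  ),
  nrow = 8, byrow = TRUE,
  dimnames = list(.qed_properties, c("a", "b", "c", "d", "e", "f", "dmax"))
)

# Published mean-optimal weight set (QED_w,mo); the unweighted variant uses
# equal weights.
.qed_weights_mean <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                       PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERT = 0.95)

# Desirabilities are floored at this value before taking logs, so QED is
# strictly positive even for extreme descriptor values.
.qed_desirability_floor <- 0.003

#' Desirability of one physicochemical descriptor
#'
#' Evaluates the published asymmetric double-sigmoid desirability function for
#' one of the eight QED descriptors, normalized by the function's maximum so
#' the most drug-like value of the descriptor scores 1.
#'
#' @param property One of `"MW"`, `"ALOGP"`, `"HBA"`, `"HBD"`, `"PSA"`,
#'   `"ROTB"`, `"AROM"`, `"ALERT"`.
#' @param x Numeric vector of descriptor values.
#'
#' @return Numeric vector of desirabilities in (0, 1].
#' @examples
#' qed_desirability("MW", c(300, 700))
#' @export
qed_desirability <- function(property, x) {
  if (!is.character(property) || length(property) != 1L ||
      !property %in% .qed_properties) {
    abort(sprintf("unknown QED property `%s`; expected one of %s",
                  paste(property, collapse = ","),
                  paste(.qed_properties, collapse = ", ")),
          class = "herbnet_parameter_error")
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("descriptor values must be finite numbers", class = "herbnet_domain_error")
  }
  p <- .qed_ads_params[property, ]
  sig1 <- 1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])
  sig2 <- 1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])
  dx <- p[["a"]] + p[["b"]] / sig1 * (1 - 1 / sig2)
  pmin(dx / p[["dmax"]], 1)
}

#' QED drug-likeness score
#'
#' Computes the quantitative estimate of drug-likeness: the exponential of the
#' weighted mean of log-desirabilities, `exp(sum(w * log(d)) / sum(w))`. With
#' equal weights this is the geometric mean of the eight desirabilities.
#'
#' @param descriptors Data frame with numeric columns `MW`, `ALOGP`, `HBA`,
#'   `HBD`, `PSA`, `ROTB`, `AROM`, `ALERT` (one row per compound).
#' @param weights `"unweighted"` (equal weights, the default), `"mean"` (the
#'   published mean-optimal weight set), or a named non-negative numeric
#'   vector over the eight properties.
#'
#' @return Numeric vector of QED values in (0, 1], one per row.
#' @examples
#' qed_score(data.frame(MW = 300, ALOGP = 2.5, HBA = 3, HBD = 1,
#'                      PSA = 60, ROTB = 3, AROM = 2, ALERT = 0))
#' @export
qed_score <- function(descriptors, weights = "unweighted") {
  assert_columns(descriptors, .qed_properties, "descriptors")
  w <- resolve_qed_weights(weights)
  logd <- vapply(.qed_properties, function(prop) {
    d <- qed_desirability(prop, descriptors[[prop]])
    log(pmax(d, .qed_desirability_floor))
  }, numeric(nrow(descriptors)))
  logd <- matrix(logd, nrow = nrow(descriptors))
  exp(as.vector(logd %*% w) / sum(w))
}

resolve_qed_weights <- function(weights) {
  if (is.character(weights) && length(weights) == 1L) {
    return(switch(weights,
      unweighted = setNames(rep(1, 8L), .qed_properties),
      mean = .qed_weights_mean,
      abort(sprintf("unknown weight set `%s`", weights),
            class = "herbnet_parameter_error")
    ))
  }
  if (!is.numeric(weights) || is.null(names(weights)) ||
      !setequal(names(weights), .qed_properties) ||
      any(weights < 0) || all(weights == 0)) {
    abort("`weights` must name all eight properties, be non-negative, and not all zero",
          class = "herbnet_parameter_error")
  }
  weights[.qed_properties]
}

#' Veber oral-bioavailability rule
#'
#' A compound passes when ROTB <= 10, HBA + HBD <= 12 and PSA <= 140 A^2, all
#' boundaries inclusive.
#'
#' @param descriptors Data frame with numeric columns `ROTB`, `HBA`, `HBD`,
#'   `PSA`.
#'
#' @return Logical vector, one verdict per row.
#' @examples
#' veber_pass(data.frame(ROTB = 10, HBA = 6, HBD = 6, PSA = 140))
#' @export
veber_pass <- function(descriptors) {
  assert_columns(descriptors, c("ROTB", "HBA", "HBD", "PSA"), "descriptors")
  descriptors$ROTB <= 10 &
    (descriptors$HBA + descriptors$HBD) <= 12 &
    descriptors$PSA <= 140
}

#' Screen compounds for expected active compounds (EAC)
#'
#' Applies the QED drug-likeness and Veber oral-bioavailability screens to a
#' compound table and flags expected active compounds: those with
#' `qed >= qed_min` and a passing Veber verdict.
#'
#' @param compounds Data frame with a unique `compound_id` column and the
#'   eight descriptor columns (`MW`, `ALOGP`, `HBA`, `HBD`, `PSA`, `ROTB`,
#'   `AROM`, `ALERT`). Extra columns are ignored.
#' @param qed_min QED cutoff (default 0.3).
#' @param weights Passed to [qed_score()].
#'
#' @return A tibble with columns `compound_id`, `qed`, `veber_ok`, `is_eac`,
#'   in input order.
#' @export
screen_compounds <- function(compounds, qed_min = 0.3, weights = "unweighted") {
  assert_columns(compounds, c("compound_id", .qed_properties), "compounds")
  if (anyDuplicated(compounds$compound_id)) {
    abort("`compounds$compound_id` contains duplicate ids",
          class = "herbnet_input_error")
  }
  assert_scalar_number(qed_min, "qed_min", min = 0, max = 1)
  desc <- compounds[.qed_properties]
  if (any(!vapply(desc, is.numeric, logical(1)))) {
    abort("descriptor columns must be numeric", class = "herbnet_domain_error")
  }
  qed <- qed_score(desc, weights = weights)
  veber <- veber_pass(desc)
  tibble(
    compound_id = compounds$compound_id,
    qed = qed,
    veber_ok = veber,
    is_eac = qed >= qed_min & veber
  )
}
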