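# Monoisotopic mass and adduct m/z arithmetic for negative-mode ESI
# identification ("find by formula" style matching at a ppm tolerance).

# Monoisotopic (most abundant isotope) atomic masses, Da.
.monoisotopic_masses <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  F  = 18.99840320,
  Cl = 34.96885271,
  Br = 78.9183376,
  I  = 126.904468,
  Na = 22.98976928,
  K  = 38.9637069,
  Si = 27.9769265327
)

.electron_mass <- 0.00054858

# Adduct registry: mass delta relative to the neutral molecule and the atoms
# the molecule must contain. The default [M-H]- uses the neutral-hydrogen
# convention (no electron-mass term), which is how vendor "calculated m/z"
# columns are commonly produced.
.adducts <- list(
  "[M-H]-" = list(delta = -.monoisotopic_masses[["H"]],
                  electron_sign = +1,  # gains an electron on deprotonation
                  requires = c(H = 1L))
)

#' Parse a molecular formula
#'
#' Parses a Hill-notation-like formula string (e.g. `"C15H10O5"`) into
#' element counts. Repeated element tokens are summed.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts, in Hill order (C, H, then
#'   alphabetical).
#' @examples
#' parse_formula("C15H10O5")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single formula string", class = "herbnet_parse_error")
  }
  s <- gsub("[[:space:]]", "", text)
  if (s == "") {
    return(setNames(integer(), character()))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    abort(sprintf("malformed formula `%s`", text), class = "herbnet_parse_error")
  }
  el <- sub("[0-9]*$", "", tokens)
  ct <- sub("^[A-Za-z]+", "", tokens)
  ct <- ifelse(ct == "", 1L, as.integer(ct))
  unknown <- setdiff(el, names(.monoisotopic_masses))
  if (length(unknown)) {
    abort(sprintf("unknown element(s) in `%s`: %s", text,
                  paste(unknown, collapse = ", ")),
          class = "herbnet_parse_error")
  }
  if (any(ct < 1L)) {
    abort(sprintf("element counts must be positive in `%s`", text),
          class = "herbnet_parse_error")
  }
  counts <- tapply(ct, el, sum)
  counts <- setNames(as.integer(counts), names(counts))
  hill <- c(intersect(c("C", "H"), names(counts)),
            sort(setdiff(names(counts), c("C", "H"))))
  counts[hill]
}

#' Serialize element counts back to a formula string
#'
#' Inverse of [parse_formula()]; counts of 1 are written without a digit.
#'
#' @param counts Named integer vector of element counts.
#' @return A single formula string in Hill order.
#' @export
format_formula <- function(counts) {
  if (length(counts) == 0L) return("")
  hill <- c(intersect(c("C", "H"), names(counts)),
            sort(setdiff(names(counts), c("C", "H"))))
  counts <- counts[hill]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

as_formula_counts <- function(f) {
  if (is.character(f)) parse_formula(f) else {
    if (is.null(names(f)) && length(f) > 0L) {
      abort("formula counts must be named by element", class = "herbnet_parse_error")
    }
    f
  }
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count times most-abundant-isotope mass over the elements, from the
#' packaged monoisotopic mass table.
#'
#' @param f Formula string or named count vector from [parse_formula()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(f) {
  counts <- as_formula_counts(f)
  if (length(counts) == 0L) return(0)
  unknown <- setdiff(names(counts), names(.monoisotopic_masses))
  if (length(unknown)) {
    abort(sprintf("unknown element(s): %s", paste(unknown, collapse = ", ")),
          class = "herbnet_parse_error")
  }
  sum(.monoisotopic_masses[names(counts)] * as.numeric(counts))
}

#' Adduct m/z of a molecular formula
#'
#' m/z of the adduct ion. For the deprotonated ion `[M-H]-` the default is
#' the neutral-hydrogen convention: monoisotopic mass minus the hydrogen atom
#' mass (1.0078250319 Da), with no electron-mass term. Setting
#' `electron_correction = TRUE` adds the electron mass the anion physically
#' carries (+0.00054858 Da).
#'
#' @param f Formula string or named count vector.
#' @param adduct Adduct name; `"[M-H]-"` is currently registered.
#' @param electron_correction Apply the electron-mass term (default `FALSE`).
#' @return m/z value.
#' @examples
#' adduct_mz("C15H10O5") # deprotonated apigenin
#' @export
adduct_mz <- function(f, adduct = "[M-H]-", electron_correction = FALSE) {
  if (!adduct %in% names(.adducts)) {
    abort(sprintf("unknown adduct `%s`", adduct), class = "herbnet_parameter_error")
  }
  counts <- as_formula_counts(f)
  spec <- .adducts[[adduct]]
  req <- spec$requires
  for (el in names(req)) {
    have <- if (el %in% names(counts)) counts[[el]] else 0L
    if (have < req[[el]]) {
      abort(sprintf("adduct %s requires %d %s atom(s); formula has %d",
                    adduct, req[[el]], el, have),
            class = "herbnet_domain_error")
    }
  }
  mz <- monoisotopic_mass(counts) + spec$delta
  if (isTRUE(electron_correction)) {
    mz <- mz + spec$electron_sign * .electron_mass
  }
  unname(mz)
}

#' Mass accuracy in parts per million
#'
#' `(observed - calculated) / calculated * 1e6`; negative when the observed
#' value is below the calculated one.
#'
#' @param observed,calculated m/z values (vectors recycle).
#' @return ppm error.
#' @export
ppm_error <- function(observed, calculated) {
  if (any(!is.finite(calculated)) || any(calculated <= 0)) {
    abort("`calculated` must be positive", class = "herbnet_domain_error")
  }
  (observed - calculated) / calculated * 1e6
}

#' Match observed peaks to formula candidates
#'
#' Computes the `[M-H]-` m/z of every candidate and reports, for each peak,
#' all candidates within the ppm tolerance. Peaks with no candidate in
#' tolerance are kept with `NA` match columns so nothing is silently lost.
#'
#' @param peaks Data frame with columns `rt_min`, `mz`.
#' @param candidates Data frame with columns `name`, `formula`.
#' @param tol_ppm Match tolerance in ppm (default 10).
#' @param adduct Adduct assumed for all candidates.
#'
#' @return A tibble with columns `rt_min`, `observed_mz`, `name`, `formula`,
#'   `calculated_mz`, `error_ppm`, `matched`.
#' @export
match_peaks <- function(peaks, candidates, tol_ppm = 10, adduct = "[M-H]-") {
  assert_columns(peaks, c("rt_min", "mz"), "peaks")
  assert_columns(candidates, c("name", "formula"), "candidates")
  assert_scalar_number(tol_ppm, "tol_ppm")
  if (tol_ppm <= 0) {
    abort("`tol_ppm` must be positive", class = "herbnet_domain_error")
  }
  cand <- tibble(
    name = candidates$name,
    formula = candidates$formula,
    calculated_mz = vapply(candidates$formula, function(f) adduct_mz(f, adduct),
                           numeric(1), USE.NAMES = FALSE)
  )
  rows <- purrr::pmap(peaks[c("rt_min", "mz")], function(rt_min, mz) {
    err <- ppm_error(mz, cand$calculated_mz)
    hit <- which(abs(err) <= tol_ppm)
    if (length(hit) == 0L) {
      tibble(rt_min = rt_min, observed_mz = mz, name = NA_character_,
             formula = NA_character_, calculated_mz = NA_real_,
             error_ppm = NA_real_, matched = FALSE)
    } else {
      tibble(rt_min = rt_min, observed_mz = mz, name = cand$name[hit],
             formula = cand$formula[hit], calculated_mz = cand$calculated_mz[hit],
             error_ppm = err[hit], matched = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}
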