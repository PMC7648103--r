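# Accurate-mass chemistry: formulas, monoisotopic masses, adducts, ppm matching.

# Monoisotopic (most abundant isotope) atomic masses, Da. CODATA/IUPAC values,
# >= 6 decimals; rounding happens only at report time.
ELEMENT_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Se = 79.9165213,
  Si = 27.9769265325
)

ELECTRON_MASS <- 0.000548579909  # Da
PROTON_MASS <- ELEMENT_MASSES[["H"]] - ELECTRON_MASS

#' Parse an elemental formula string
#'
#' Parses formulas written in the usual condensed notation (e.g. `"C6H6N2O"`)
#' into named element counts. An omitted count means 1. Only elements with a
#' defined monoisotopic mass are accepted.
#'
#' @param text A single formula string.
#' @return A named integer vector of element counts.
#' @examples
#' parse_formula("C6H6N2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    stop("empty formula string", call. = FALSE)
  }
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (paste(tokens, collapse = "") != text) {
    stop("malformed formula string: ", text, call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Z][a-z]?", "", tokens)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  unknown <- setdiff(sym, names(ELEMENT_MASSES))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(cnt < 1L)) stop("element counts must be >= 1", call. = FALSE)
  counts <- tapply(cnt, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  hill_order(out)
}

# Hill convention: C first, then H, then remaining symbols alphabetically;
# if no carbon, everything alphabetical.
hill_order <- function(counts) {
  sym <- names(counts)
  if ("C" %in% sym) {
    ord <- c(intersect(c("C", "H"), sym), sort(setdiff(sym, c("C", "H"))))
  } else {
    ord <- sort(sym)
  }
  counts[ord]
}

#' Write element counts as a canonical Hill-order formula string
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return A single string, e.g. `"C6H6N2O"`.
#' @export
formula_to_string <- function(counts) {
  counts <- hill_order(counts)
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of element counts times monoisotopic atomic masses.
#'
#' @param formula A formula string or a named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")  # 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) return(0)
  unknown <- setdiff(names(formula), names(ELEMENT_MASSES))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(ELEMENT_MASSES[names(formula)] * formula)
}

#' Supported electrospray adducts
#'
#' The singly charged adducts considered during annotation. `mass_delta` is
#' the signed mass added to the neutral monoisotopic mass and already includes
#' the electron gained or lost with the charge (so `[M+H]+` adds a proton,
#' 1.007276 Da, not a hydrogen atom).
#'
#' @return A tibble with columns `adduct`, `mass_delta` (Da) and `charge`.
#' @export
common_adducts <- function() {
  h2o <- 2 * ELEMENT_MASSES[["H"]] + ELEMENT_MASSES[["O"]]
  nh4 <- ELEMENT_MASSES[["N"]] + 4 * ELEMENT_MASSES[["H"]]
  tibble::tibble(
    adduct = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+",
               "[M+H-H2O]+", "[M+NH4-H2O]+", "[M-H]-"),
    mass_delta = c(
      PROTON_MASS,
      ELEMENT_MASSES[["Na"]] - ELECTRON_MASS,
      ELEMENT_MASSES[["K"]] - ELECTRON_MASS,
      nh4 - ELECTRON_MASS,
      PROTON_MASS - h2o,
      nh4 - ELECTRON_MASS - h2o,
      -PROTON_MASS
    ),
    charge = c(1L, 1L, 1L, 1L, 1L, 1L, -1L)
  )
}

#' Theoretical m/z of an adduct ion
#'
#' `(monoisotopic mass + mass_delta) / |charge|` for each formula/adduct pair.
#' Vectorized over both arguments (recycled to a common length).
#'
#' @param formula Formula string(s).
#' @param adduct Adduct name(s); see [common_adducts()].
#' @return Theoretical m/z in Th.
#' @examples
#' adduct_mz("C6H6N2O", "[M+H]+")  # 123.0553, niacinamide
#' @export
adduct_mz <- function(formula, adduct) {
  specs <- common_adducts()
  idx <- match(adduct, specs$adduct)
  if (anyNA(idx)) {
    stop("unsupported adduct(s): ",
         paste(unique(adduct[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  n <- max(length(formula), length(adduct))
  formula <- rep_len(formula, n)
  idx <- rep_len(idx, n)
  mono <- vapply(formula, monoisotopic_mass, numeric(1), USE.NAMES = FALSE)
  (mono + specs$mass_delta[idx]) / abs(specs$charge[idx])
}

#' Signed mass error in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values in Th.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}

#' Annotate feature m/z values against a candidate list
#'
#' Compares every feature m/z to every candidate x adduct theoretical m/z and
#' keeps combinations within a ppm tolerance. Results are sorted, within each
#' feature, by absolute ppm error; ties break lexicographically by candidate
#' name so output is invariant to the candidate-list order.
#'
#' @param features A data frame with a numeric `mz` column (or a bare numeric
#'   vector of m/z values).
#' @param candidates A data frame with columns `name` and `formula` (Hill
#'   notation), e.g. from [read_candidates()].
#' @param adducts Character vector of adduct names to try; defaults to the
#'   positive-mode set.
#' @param tol_ppm Match tolerance in ppm (default 10; use 5 for
#'   high-confidence accurate-mass annotation).
#' @return A tibble with columns `feature_mz`, `name`, `formula`, `adduct`,
#'   `theoretical_mz`, `ppm_error`; zero rows if nothing matches.
#' @export
annotate_features <- function(features, candidates,
                              adducts = c("[M+H]+", "[M+Na]+", "[M+K]+",
                                          "[M+NH4]+"),
                              tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  mzs <- if (is.data.frame(features)) features$mz else features
  stopifnot(is.numeric(mzs))
  if (nrow(candidates %||% tibble::tibble()) == 0L || length(mzs) == 0L) {
    return(tibble::tibble(feature_mz = numeric(), name = character(),
                          formula = character(), adduct = character(),
                          theoretical_mz = numeric(), ppm_error = numeric()))
  }
  grid <- tidyr::expand_grid(
    candidates[c("name", "formula")],
    adduct = adducts
  )
  grid$theoretical_mz <- adduct_mz(grid$formula, grid$adduct)
  hits <- tidyr::expand_grid(feature_mz = mzs, grid)
  hits$ppm_error <- ppm_error(hits$feature_mz, hits$theoretical_mz)
  hits <- hits[abs(hits$ppm_error) <= tol_ppm, , drop = FALSE]
  hits <- dplyr::arrange(hits, .data$feature_mz, abs(.data$ppm_error),
                         .data$name, .data$adduct)
  tibble::as_tibble(hits[c("feature_mz", "name", "formula", "adduct",
                           "theoretical_mz", "ppm_error")])
}

#' Read a candidate metabolite list from CSV
#'
#' Expects columns `name` and `formula`.
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_candidates <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("name", "formula") %in% names(out))) {
    stop("candidate CSV needs 'name' and 'formula' columns", call. = FALSE)
  }
  out
}

#' Write annotation hits to CSV
#'
#' @param hits Tibble from [annotate_features()].
#' @param path Output CSV path.
#' @return `hits`, invisibly.
#' @export
write_annotations <- function(hits, path) {
  readr::write_csv(hits, path)
  invisible(hits)
}

# Report-time rounding, half-up at `digits` decimals (printing convention for
# theoretical m/z tables).
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
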