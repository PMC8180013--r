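# Conventional atomic weights, sufficient for the sugars, polyols and the
# usual N/S/P-bearing media components.
ATOMIC_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06)

#' Parse an empirical formula
#'
#' @param formula A Hill-style empirical formula such as `"C6H12O6"`.
#' @return Named integer vector of element counts.
#' @export
parse_empirical_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse empirical formula: ", sQuote(formula), call. = FALSE)
  elements <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  out <- c(tapply(counts, elements, sum))   # plain named vector
  storage.mode(out) <- "integer"
  out[order(names(out))]
}

#' Describe a carbon source
#'
#' @param name Substrate label, e.g. `"glucose"`.
#' @param formula Empirical formula of the anhydrous compound,
#'   e.g. `"C6H12O6"`.
#' @param mass_concentration Mass concentration in the medium, g/L
#'   (default 0.4, the concentration used with Davis minimal medium).
#' @return A `carbon_source` object.
#' @export
carbon_source <- function(name, formula, mass_concentration = 0.4) {
  counts <- parse_empirical_formula(formula)
  if (is.na(counts["C"]) || counts["C"] < 1L)
    stop("a carbon source must contain at least one carbon atom", call. = FALSE)
  if (!is.numeric(mass_concentration) || mass_concentration <= 0)
    stop("mass_concentration must be positive (g/L)", call. = FALSE)
  structure(list(name = name, formula = formula, counts = counts,
                 mass_concentration = mass_concentration),
            class = "carbon_source")
}

#' Molar mass of an empirical formula
#'
#' @param formula Formula string or named count vector.
#' @return Molar mass in g/mol, from conventional atomic weights
#'   (C 12.011, H 1.008, O 15.999, ...).
#' @export
molar_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_empirical_formula(formula)
            else formula
  unknown <- setdiff(names(counts), names(ATOMIC_WEIGHTS))
  if (length(unknown))
    stop("no atomic weight for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sum(ATOMIC_WEIGHTS[names(counts)] * counts)
}

#' Millimolar concentration of carbon atoms in a medium
#'
#' Converts a substrate's mass concentration to the molarity of carbon atoms
#' it supplies: `1000 * mass_concentration / molar_mass * n_carbons` (mM of
#' C). This is the bookkeeping that makes the six media nearly equimolar in
#' carbon at 0.4 g/L (13.3 mM C for the hexoses, 13.0 for glycerol, 14.0 for
#' the disaccharides, to three significant figures).
#'
#' @param source A [carbon_source()].
#' @return Unrounded mM of carbon atoms; use `signif(x, 3)` for display.
#' @export
#' @examples
#' signif(carbon_molarity(carbon_source("glucose", "C6H12O6")), 3)  # 13.3
carbon_molarity <- function(source) {
  stopifnot(inherits(source, "carbon_source"))
  1000 * source$mass_concentration / molar_mass(source$counts) *
    as.numeric(source$counts["C"])
}

#' The six Davis-medium carbon sources of the default design
#'
#' Fructose, galactose, glucose (hexoses), glycerol, and the disaccharides
#' maltose and trehalose (anhydrous formulas), each at 0.4 g/L.
#'
#' @return Named list of [carbon_source()] objects in design order.
#' @export
davis_carbon_sources <- function() {
  list(
    fructose  = carbon_source("fructose",  "C6H12O6"),
    galactose = carbon_source("galactose", "C6H12O6"),
    glucose   = carbon_source("glucose",   "C6H12O6"),
    glycerol  = carbon_source("glycerol",  "C3H8O3"),
    maltose   = carbon_source("maltose",   "C12H22O11"),
    trehalose = carbon_source("trehalose", "C12H22O11")
  )
}

#' @export
print.carbon_source <- function(x, ...) {
  cat(x$name, " (", x$formula, ", ", x$mass_concentration, " g/L): ",
      signif(carbon_molarity(x), 3), " mM of carbon atoms\n", sep = "")
  invisible(x)
}
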