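#' Define a mutation-accumulation assay design
#'
#' An assay design fixes the labels and ordering of everything the pipeline
#' iterates over: the MA genotypes, the ancestral strain they are scored
#' against, the carbon substrates (the "environments" of the G-by-E
#' partition), the assay temperatures and the number of technical replicates.
#' All downstream tables and matrices use the orders given here.
#'
#' @param genotypes Character vector of MA genotype labels (at least 2).
#' @param carbons Character vector of carbon substrate labels (at least 2).
#' @param temperatures Numeric vector of assay temperatures in degrees
#'   Celsius, strictly increasing.
#' @param replicates Number of technical replicates per culture (>= 1).
#' @param ancestor Label reserved for the ancestral strain; must not appear
#'   among `genotypes`.
#'
#' @return An object of class `ma_design`: a list with elements `genotypes`,
#'   `ancestor`, `carbons`, `temperatures` and `replicates`.
#'
#' @details Variance partitioning is undefined with fewer than two genotypes
#'   or two environments, so those minima are enforced here, before any data
#'   is read.
#'
#' @seealso [default_design()] for the 10-genotype, 6-substrate,
#'   10-temperature layout used throughout the documentation.
#' @export
#' @examples
#' experiment_design(c("MA01", "MA02"), c("glucose", "maltose"), c(31, 37))
experiment_design <- function(genotypes, carbons, temperatures,
                              replicates = 3L, ancestor = "ancestor") {
  genotypes <- as.character(genotypes)
  carbons <- as.character(carbons)
  temperatures <- as.numeric(temperatures)
  replicates <- as.integer(replicates)
  if (length(genotypes) < 2L)
    stop("at least 2 MA genotypes are required (variance partitioning is ",
         "undefined below G = 2)", call. = FALSE)
  if (length(carbons) < 2L)
    stop("at least 2 carbon substrates are required (E >= 2)", call. = FALSE)
  if (anyDuplicated(genotypes))
    stop("duplicate genotype labels: ",
         paste(unique(genotypes[duplicated(genotypes)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(carbons))
    stop("duplicate carbon labels: ",
         paste(unique(carbons[duplicated(carbons)]), collapse = ", "),
         call. = FALSE)
  if (length(ancestor) != 1L || !nzchar(ancestor))
    stop("'ancestor' must be a single non-empty label", call. = FALSE)
  if (ancestor %in% genotypes)
    stop("the ancestor label ", sQuote(ancestor),
         " must not appear among the MA genotypes", call. = FALSE)
  if (length(temperatures) < 1L || anyNA(temperatures))
    stop("'temperatures' must be numeric and non-missing", call. = FALSE)
  if (any(diff(temperatures) <= 0))
    stop("'temperatures' must be strictly increasing with no duplicates",
         call. = FALSE)
  if (is.na(replicates) || replicates < 1L)
    stop("'replicates' must be a positive integer", call. = FALSE)
  structure(
    list(genotypes = genotypes, ancestor = as.character(ancestor),
         carbons = carbons, temperatures = temperatures,
         replicates = replicates),
    class = "ma_design"
  )
}

#' Default assay design: 10 MA genotypes, 6 substrates, 10 temperatures
#'
#' One ancestor plus ten MA genotypes assayed on six carbon substrates
#' (fructose, galactose, glucose, glycerol, maltose, trehalose, each at
#' 0.4 g/L in Davis minimal medium) at ten temperatures from 23 to 41 degrees
#' Celsius in 2-degree steps, with three technical replicates.
#'
#' @return An `ma_design` object.
#' @export
default_design <- function() {
  experiment_design(
    genotypes = sprintf("MA%02d", 1:10),
    carbons = c("fructose", "galactose", "glucose", "glycerol",
                "maltose", "trehalose"),
    temperatures = seq(23, 41, by = 2),
    replicates = 3L,
    ancestor = "ancestor"
  )
}

#' @export
print.ma_design <- function(x, ...) {
  cat("Assay design:", length(x$genotypes), "MA genotypes + ancestor",
      sQuote(x$ancestor), "\n")
  cat("  carbons (", length(x$carbons), "): ",
      paste(x$carbons, collapse = ", "), "\n", sep = "")
  cat("  temperatures (", length(x$temperatures), " C): ",
      paste(format(x$temperatures), collapse = ", "), "\n", sep = "")
  cat("  technical replicates:", x$replicates, "\n")
  invisible(x)
}

# Index of a temperature within the design, matched with a small absolute
# tolerance so CSV round-trips of plain Celsius values never miss.
match_temperature <- function(t, design, tol = 1e-8) {
  vapply(t, function(ti) {
    j <- which(abs(design$temperatures - ti) < tol)
    if (length(j)) j[1L] else NA_integer_
  }, integer(1))
}

env_key <- function(carbon, temperature_c) {
  paste(carbon, sprintf("%.6f", as.numeric(temperature_c)), sep = "@")
}
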