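#' @importFrom utils read.csv write.csv
NULL

MEASUREMENT_COLUMNS <- c("genotype", "carbon", "temperature_c",
                         "replicate", "mOD", "is_blank")

#' Read raw plate-reader measurements
#'
#' Reads the canonical long-format CSV of raw milli-OD readings and validates
#' every record against the assay design before anything downstream runs.
#' The schema has one row per well reading with columns
#' `genotype,carbon,temperature_c,replicate,mOD,is_blank`; blank (medium-only)
#' wells carry `is_blank = TRUE` and an empty genotype field.
#'
#' @param path Path to a CSV file with the schema above (UTF-8, comma
#'   delimited, header row mandatory, dot decimal separator).
#' @param design An [experiment_design()] the records must conform to.
#'
#' @return A `data.frame` of validated measurement records, one row per
#'   reading, in file order.
#'
#' @details Validation enforces: all labels and temperatures known to the
#'   design; non-negative finite mOD; at least one blank row in every
#'   (carbon, temperature) assay environment that has culture readings; and
#'   the ancestor present in every such environment. Any violation raises an
#'   error naming the offending rows or environments.
#' @export
read_measurements <- function(path, design) {
  stopifnot(inherits(design, "ma_design"))
  if (!file.exists(path))
    stop("measurement file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(genotype = "character", carbon = "character"))
  if (!identical(names(df), MEASUREMENT_COLUMNS))
    stop("unexpected header in ", path, ": expected columns ",
         paste(MEASUREMENT_COLUMNS, collapse = ","), ", found ",
         paste(names(df), collapse = ","), call. = FALSE)
  df$genotype[is.na(df$genotype)] <- ""
  df$temperature_c <- as.numeric(df$temperature_c)
  df$replicate <- as.integer(df$replicate)
  df$mOD <- as.numeric(df$mOD)
  df$is_blank <- parse_logical(df$is_blank, "is_blank")
  validate_measurements(df, design)
  df
}

parse_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1")] <- TRUE
  out[lx %in% c("false", "f", "0")] <- FALSE
  if (anyNA(out))
    stop("column '", what, "' has non-logical entries at rows ",
         paste(utils::head(which(is.na(out)), 5L), collapse = ", "),
         call. = FALSE)
  out
}

#' Validate measurement records against a design
#'
#' Checks the experimental-design invariants of a record table: known labels
#' and temperatures, non-negative readings, positive replicate indices, a
#' blank present in every assayed environment and the ancestor present in
#' every environment that has culture readings. Called by
#' [read_measurements()]; exported so programmatically built tables (e.g.
#' simulator output) can be checked the same way.
#'
#' @param records Data frame with the measurement schema.
#' @param design An [experiment_design()].
#' @return Invisibly `TRUE`; errors describe every violation class found.
#' @export
validate_measurements <- function(records, design) {
  stopifnot(is.data.frame(records), inherits(design, "ma_design"))
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  geno <- as.character(records$genotype)
  geno[is.na(geno)] <- ""
  blank <- records$is_blank

  bad <- which(blank & nzchar(geno))
  if (length(bad))
    stop("blank rows must have an empty genotype; offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!blank & !geno %in% c(design$ancestor, design$genotypes))
  if (length(bad))
    stop("unknown genotype label(s) ",
         paste(sQuote(unique(geno[bad])), collapse = ", "),
         " at row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  bad <- which(!records$carbon %in% design$carbons)
  if (length(bad))
    stop("unknown carbon label(s) ",
         paste(sQuote(unique(records$carbon[bad])), collapse = ", "),
         " at row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  ti <- match_temperature(records$temperature_c, design)
  if (anyNA(ti))
    stop("temperature(s) not in design: ",
         paste(unique(format(records$temperature_c[is.na(ti)])),
               collapse = ", "),
         " at row(s) ",
         paste(utils::head(which(is.na(ti)), 5L), collapse = ", "),
         call. = FALSE)
  if (anyNA(records$mOD) || any(!is.finite(records$mOD)) ||
      any(records$mOD < 0))
    stop("mOD readings must be finite and non-negative; offending rows: ",
         paste(utils::head(which(!is.finite(records$mOD) |
                                   records$mOD < 0), 5L), collapse = ", "),
         call. = FALSE)
  if (anyNA(records$replicate) || any(records$replicate < 1L))
    stop("replicate indices must be positive integers", call. = FALSE)

  key <- env_key(records$carbon, records$temperature_c)
  culture_envs <- unique(key[!blank])
  blank_envs <- unique(key[blank])
  no_blank <- setdiff(culture_envs, blank_envs)
  if (length(no_blank))
    stop("no blank reading for assay environment(s): ",
         paste(sub("@", " at ", no_blank), collapse = "; "), call. = FALSE)
  anc_envs <- unique(key[!blank & geno == design$ancestor])
  no_anc <- setdiff(culture_envs, anc_envs)
  if (length(no_anc))
    stop("ancestor ", sQuote(design$ancestor),
         " missing in assay environment(s): ",
         paste(sub("@", " at ", no_anc), collapse = "; "), call. = FALSE)
  invisible(TRUE)
}

#' Write a tabular result to CSV
#'
#' Writes any of the pipeline's tables (measurements, scores, variance
#' components, classifications, rank curves) as a plain CSV with stable
#' column order. Real-valued columns are serialized with 12 significant
#' digits so a write-read round trip is lossless at analysis precision
#' (absolute error below 1e-9 for the score scale used here).
#'
#' @param x A data frame whose rows share one schema.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.12g", out[[j]])
    else out[[j]] <- as.character(out[[j]])
    if (any(grepl("[\",\n]", out[[j]])))
      stop("field values may not contain commas, quotes or newlines ",
           "(column ", sQuote(names(out)[j]), ")", call. = FALSE)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a score table written by the pipeline
#'
#' @param path CSV with at least columns `genotype,carbon,temperature_c,score`.
#' @param design The [experiment_design()] the scores belong to; attached to
#'   the result so matrix builders know the row/column orders.
#' @return An `ma_scores` data frame.
#' @export
read_scores <- function(path, design) {
  stopifnot(inherits(design, "ma_design"))
  if (!file.exists(path)) stop("score file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "carbon", "temperature_c", "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("score file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$genotype), design$genotypes)
  if (length(bad))
    stop("unknown genotype label(s) in score file: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$carbon), design$carbons)
  if (length(bad))
    stop("unknown carbon label(s) in score file: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  if (anyNA(match_temperature(df$temperature_c, design)))
    stop("score file contains temperatures not in the design", call. = FALSE)
  structure(df, design = design, class = c("ma_scores", "data.frame"))
}
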