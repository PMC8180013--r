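#' Subtract a blank reading from a raw mOD value
#'
#' The background (medium-only) milli-OD is subtracted from each culture
#' reading; the result is clamped at zero so a blank slightly exceeding a
#' near-empty well can never produce a negative yield. Vectorised with the
#' usual recycling.
#'
#' @param raw_mOD Non-negative raw reading(s), milli-OD at 600 nm.
#' @param blank_mOD Non-negative blank reading(s) for the same assay
#'   environment.
#' @return `pmax(raw_mOD - blank_mOD, 0)`.
#' @export
#' @examples
#' subtract_blank(250, 40)  # 210
#' subtract_blank(30, 40)   # 0, clamped
subtract_blank <- function(raw_mOD, blank_mOD) {
  if (any(raw_mOD < 0, na.rm = TRUE) || any(blank_mOD < 0, na.rm = TRUE))
    stop("mOD readings must be non-negative", call. = FALSE)
  pmax(raw_mOD - blank_mOD, 0)
}

#' Average technical replicates
#'
#' Technical replicates of one genotype in one assay environment are
#' averaged on the net (blank-corrected) mOD scale; the replicate means, not
#' the individual wells, enter all downstream analysis.
#'
#' @param values Numeric vector of net mOD values, at least one.
#' @param cell Optional label used in the error message when `values` is
#'   empty (e.g. `"MA03/glucose/31"`).
#' @return The arithmetic mean.
#' @export
average_replicates <- function(values, cell = NULL) {
  if (length(values) == 0L || anyNA(values))
    stop("no replicate values",
         if (!is.null(cell)) paste0(" for cell ", cell), call. = FALSE)
  mean(values)
}

#' Relative growth performance score
#'
#' The score of an MA genotype against the ancestor in one assay environment
#' is `log10((mOD_MA + 1) / (mOD_ancestor + 1))`, both values being
#' blank-corrected replicate means. The +1 offset keeps the ratio defined
#' when a culture reads zero. A positive score indicates increased growth
#' performance relative to the ancestor, a negative score a loss.
#'
#' @param mOD_ma_net Mean net mOD of the MA genotype (>= 0).
#' @param mOD_anc_net Mean net mOD of the ancestor in the same environment
#'   (>= 0).
#' @return The dimensionless log10 score; 0 iff the two nets are equal.
#' @export
#' @examples
#' relative_growth_score(99, 199)   # log10(100/200) = -0.30103
#' relative_growth_score(0, 0)      # 0, the case the +1 offset exists for
relative_growth_score <- function(mOD_ma_net, mOD_anc_net) {
  if (any(mOD_ma_net < 0, na.rm = TRUE) || any(mOD_anc_net < 0, na.rm = TRUE))
    stop("net mOD values must be non-negative", call. = FALSE)
  log10((mOD_ma_net + 1) / (mOD_anc_net + 1))
}

#' Build the score table from raw measurements
#'
#' For every MA genotype in every (carbon, temperature) assay environment:
#' subtract that environment's mean blank from each replicate reading,
#' average the replicates, and form the relative growth performance score
#' against the ancestor's replicate mean from the same environment.
#'
#' @param records Validated measurement records
#'   (see [read_measurements()]).
#' @param design The [experiment_design()].
#' @param score_then_average If `TRUE`, scores are computed per replicate
#'   (against the ancestor replicate mean) and then averaged, instead of the
#'   default average-then-score. Exposed as a sensitivity switch; the
#'   default treats the replicate mean as the measurement being scored.
#' @param clamp If `TRUE` (default) blank subtraction clamps negative nets
#'   at zero; `FALSE` keeps raw differences (for sensitivity re-runs).
#' @param on_missing `"warn"` (default) or `"error"` when design cells have
#'   no readings; missing cells are always listed in the
#'   `missing_cells` attribute of the result.
#'
#' @return An `ma_scores` data frame with columns
#'   `genotype, carbon, temperature_c, score, mOD_ma_net, mOD_anc_net`,
#'   ordered by temperature, carbon, genotype (design order), carrying the
#'   design as an attribute. The ancestor itself has no score rows.
#' @export
build_score_table <- function(records, design, score_then_average = FALSE,
                              clamp = TRUE,
                              on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  validate_measurements(records, design)
  geno <- as.character(records$genotype)
  geno[is.na(geno)] <- ""
  key <- env_key(records$carbon, records$temperature_c)

  blanks <- records$is_blank
  blank_mean <- tapply(records$mOD[blanks], key[blanks], mean)

  cult <- !blanks
  net <- records$mOD[cult] - blank_mean[key[cult]]
  if (clamp) net <- pmax(net, 0)
  cell <- data.frame(genotype = geno[cult], carbon = records$carbon[cult],
                     temperature_c = records$temperature_c[cult], net = net)
  cell_key <- paste(cell$genotype, env_key(cell$carbon, cell$temperature_c))
  net_mean <- tapply(cell$net, cell_key, mean)
  log_mean <- tapply(log10(cell$net + 1), cell_key, mean)

  grid <- expand.grid(genotype = design$genotypes, carbon = design$carbons,
                      temperature_c = design$temperatures,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gkey <- paste(grid$genotype, env_key(grid$carbon, grid$temperature_c))
  akey <- paste(design$ancestor, env_key(grid$carbon, grid$temperature_c))
  grid$mOD_ma_net <- unname(net_mean[gkey])
  grid$mOD_anc_net <- unname(net_mean[akey])

  miss <- is.na(grid$mOD_ma_net)
  anc_miss <- is.na(grid$mOD_anc_net) & !miss
  if (any(anc_miss))
    stop("ancestor has no readings in environment(s): ",
         paste(unique(paste(grid$carbon[anc_miss], "at",
                            grid$temperature_c[anc_miss])), collapse = "; "),
         call. = FALSE)
  missing_cells <- grid[miss, c("genotype", "carbon", "temperature_c")]
  if (nrow(missing_cells)) {
    msg <- paste0(nrow(missing_cells), " design cell(s) have no readings, ",
                  "e.g. ", missing_cells$genotype[1L], "/",
                  missing_cells$carbon[1L], "/",
                  missing_cells$temperature_c[1L])
    if (on_missing == "error") stop(msg, call. = FALSE) else warning(msg,
      call. = FALSE)
  }
  grid <- grid[!miss, , drop = FALSE]
  gkey <- gkey[!miss]
  akey <- akey[!miss]

  if (score_then_average) {
    grid$score <- unname(log_mean[gkey]) -
      log10(grid$mOD_anc_net + 1)
  } else {
    grid$score <- relative_growth_score(grid$mOD_ma_net, grid$mOD_anc_net)
  }
  if (any(!is.finite(grid$score)))
    stop("non-finite score produced; check input readings", call. = FALSE)

  ord <- order(match_temperature(grid$temperature_c, design),
               match(grid$carbon, design$carbons),
               match(grid$genotype, design$genotypes))
  grid <- grid[ord, c("genotype", "carbon", "temperature_c", "score",
                      "mOD_ma_net", "mOD_anc_net")]
  rownames(grid) <- NULL
  structure(grid, design = design, missing_cells = missing_cells,
            class = c("ma_scores", "data.frame"))
}
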