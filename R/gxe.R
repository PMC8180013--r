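#' Build a genotype-by-carbon score matrix for one temperature
#'
#' Extracts the complete G x E matrix of relative growth performance scores
#' at one assay temperature, rows ordered as the design's MA genotypes and
#' columns as its carbons. This matrix of cell means is the unit of the
#' variance partition.
#'
#' @param scores An `ma_scores` table (see [build_score_table()]).
#' @param temperature_c The assay temperature to extract.
#' @param design The [experiment_design()]; defaults to the one attached to
#'   `scores`.
#' @return A `gxe_matrix`: a numeric G x E matrix with genotype row names,
#'   carbon column names and a `temperature_c` attribute.
#' @export
build_matrix <- function(scores, temperature_c,
                         design = attr(scores, "design")) {
  if (is.null(design))
    stop("no design attached to the score table; pass 'design'",
         call. = FALSE)
  ti <- match_temperature(temperature_c, design)
  if (is.na(ti))
    stop("temperature ", format(temperature_c), " is not in the design",
         call. = FALSE)
  sub <- scores[abs(scores$temperature_c - temperature_c) < 1e-8, ,
                drop = FALSE]
  g <- length(design$genotypes)
  e <- length(design$carbons)
  m <- matrix(NA_real_, g, e,
              dimnames = list(design$genotypes, design$carbons))
  ri <- match(sub$genotype, design$genotypes)
  ci <- match(sub$carbon, design$carbons)
  keep <- !is.na(ri) & !is.na(ci)
  m[cbind(ri[keep], ci[keep])] <- sub$score[keep]
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing score for genotype ", sQuote(design$genotypes[idx[1L]]),
         ", carbon ", sQuote(design$carbons[idx[2L]]), " at ",
         format(temperature_c), " C", call. = FALSE)
  }
  structure(m, temperature_c = as.numeric(temperature_c),
            class = c("gxe_matrix", "matrix", "array"))
}

#' Per-genotype environmental statistics of a G x E matrix
#'
#' Computes, for each genotype, the environmental standard deviation of its
#' scores across carbons (sample sd, denominator E - 1) and, for each pair
#' of genotypes, the Pearson correlation of their score profiles across the
#' E carbons. These are the ingredients of the responsiveness and
#' inconsistency formulas.
#'
#' @param m A complete G x E matrix (rows genotypes, columns carbons),
#'   E >= 2.
#' @return A `gxe_env_stats` list with `sigma_E` (length-G vector) and `rho`
#'   (G x G symmetric matrix). Correlations involving a zero-variance
#'   genotype profile are undefined and stored as `NA` (flagged with a
#'   warning); they contribute nothing to inconsistency because their sigma
#'   product is zero.
#' @export
env_stats <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || ncol(m) < 2L || nrow(m) < 1L)
    stop("'m' must be a matrix with at least 2 columns", call. = FALSE)
  if (anyNA(m)) stop("'m' must be complete", call. = FALSE)
  sigma_E <- apply(m, 1L, stats::sd)
  covm <- stats::cov(t(m))        # G x G, denominator E - 1
  denom <- outer(sigma_E, sigma_E)
  rho <- ifelse(denom > 0, covm / denom, NA_real_)
  if (any(sigma_E == 0))
    warning("genotype(s) with zero environmental variance: ",
            paste(rownames(m)[sigma_E == 0], collapse = ", "),
            "; their correlations are undefined and recorded as NA",
            call. = FALSE)
  structure(list(sigma_E = sigma_E, rho = rho), class = "gxe_env_stats")
}

#' Responsiveness component of G x E variance
#'
#' Responsiveness is the part of the interaction variance that arises from
#' genotypes differing in the magnitude of their environmental variance:
#' `R = sum_{i != j} (sigma_Ei - sigma_Ej)^2 / (2 G (G - 1))`, the sum
#' running over ordered pairs of genotypes.
#'
#' @param stats An [env_stats()] result.
#' @param G Number of genotypes; defaults to `length(stats$sigma_E)`.
#' @return R, in squared-score units; zero iff all sigma_Ei are equal.
#' @export
responsiveness <- function(stats, G = length(stats$sigma_E)) {
  s <- stats$sigma_E
  if (G < 2L) stop("responsiveness requires G >= 2", call. = FALSE)
  if (G != length(s)) stop("G does not match 'stats'", call. = FALSE)
  sum(outer(s, s, "-")^2) / (2 * G * (G - 1))
}

#' Inconsistency component of G x E variance
#'
#' Inconsistency is the part of the interaction variance that arises from
#' imperfect correlation (rank changes, crossing reaction norms) of genotype
#' profiles across environments:
#' `I = sum_{i != j} sigma_Ei sigma_Ej (1 - rho_ij) / (G (G - 1))` over
#' ordered pairs. Pairs whose correlation is undefined (a zero-variance
#' profile) contribute zero, as their sigma product is zero.
#'
#' @inheritParams responsiveness
#' @return I, in squared-score units; zero when every pair has rho = 1.
#' @export
inconsistency <- function(stats, G = length(stats$sigma_E)) {
  s <- stats$sigma_E
  if (G < 2L) stop("inconsistency requires G >= 2", call. = FALSE)
  if (G != length(s)) stop("G does not match 'stats'", call. = FALSE)
  term <- outer(s, s) * (1 - stats$rho)
  term[is.na(term)] <- 0
  diag(term) <- 0
  sum(term) / (G * (G - 1))
}

#' Partition score variance at one temperature
#'
#' Method-of-moments partition of the G x E cell-mean matrix into genetic,
#' environmental and interaction components:
#' * `sigma2_G`: sample variance (denominator G - 1) of genotype (row)
#'   means;
#' * `sigma2_E`: sample variance (denominator E - 1) of carbon (column)
#'   means;
#' * `sigma2_GE`: interaction mean square
#'   `SS_int / ((G - 1)(E - 1))`, with
#'   `SS_int = sum (x_ge - rowmean_g - colmean_e + grandmean)^2`;
#' * `responsiveness` and `inconsistency` from [responsiveness()] and
#'   [inconsistency()].
#'
#' Under these sample-variance conventions the decomposition identity
#' `sigma2_GE = R + I` holds analytically; it is asserted to 1e-9 relative
#' on every call. `total` is defined as the sum of the three components, so
#' the partition is additive by construction.
#'
#' @param m A complete `gxe_matrix` (or plain G x E matrix with a
#'   `temperature_c` attribute), G >= 2, E >= 2.
#' @return A one-row data frame with columns `temperature_c, total,
#'   sigma2_G, sigma2_E, sigma2_GE, responsiveness, inconsistency`.
#' @export
partition_components <- function(m) {
  temperature_c <- attr(m, "temperature_c")
  if (is.null(temperature_c)) temperature_c <- NA_real_
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) < 2L || ncol(m) < 2L)
    stop("partitioning needs a matrix with G >= 2 and E >= 2", call. = FALSE)
  if (anyNA(m)) stop("partitioning refuses incomplete matrices", call. = FALSE)
  g <- nrow(m); e <- ncol(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  grand <- mean(m)
  sigma2_G <- stats::var(row_means)
  sigma2_E <- stats::var(col_means)
  resid <- m - outer(row_means, rep(1, e)) - outer(rep(1, g), col_means) +
    grand
  sigma2_GE <- sum(resid^2) / ((g - 1) * (e - 1))
  st <- env_stats(m)
  R <- responsiveness(st)
  I <- inconsistency(st)
  # identity tolerance is relative to the matrix's variance scale, so exact-
  # zero interaction (e.g. additive matrices) does not trip on rounding in
  # the correlations
  ident_scale <- max(sigma2_GE, max(st$sigma_E)^2, 1e-12)
  if (abs(R + I - sigma2_GE) > 1e-9 * ident_scale)
    stop("internal error: responsiveness + inconsistency does not match ",
         "the interaction mean square", call. = FALSE)
  comp <- c(sigma2_G, sigma2_E, sigma2_GE, R, I)
  if (any(comp < -1e-12))
    stop("internal error: negative variance component", call. = FALSE)
  data.frame(temperature_c = temperature_c,
             total = sigma2_G + sigma2_E + sigma2_GE,
             sigma2_G = sigma2_G, sigma2_E = sigma2_E,
             sigma2_GE = sigma2_GE,
             responsiveness = R, inconsistency = I)
}

#' Partition variance at every design temperature
#'
#' @param scores An `ma_scores` table covering the full design.
#' @param design The [experiment_design()]; defaults to the attached one.
#' @return A data frame with one [partition_components()] row per design
#'   temperature, ordered by temperature.
#' @export
partition_all <- function(scores, design = attr(scores, "design")) {
  if (is.null(design))
    stop("no design attached to the score table; pass 'design'",
         call. = FALSE)
  out <- lapply(design$temperatures, function(t)
    partition_components(build_matrix(scores, t, design)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Brute-force oracle for the interaction decomposition
#'
#' Recomputes responsiveness, inconsistency and the interaction mean square
#' by explicit double loops over ordered genotype pairs and cells, straight
#' from the defining formulas and independent of the vectorised
#' implementation in [partition_components()]. Intended for verification;
#' quadratic in G and not meant for large inputs.
#'
#' @param m A complete G x E matrix.
#' @return Named vector `c(R, I, sigma2_GE)`.
#' @export
pairwise_oracle <- function(m) {
  m <- unclass(m)
  g <- nrow(m); e <- ncol(m)
  stopifnot(g >= 2L, e >= 2L, !anyNA(m))
  sig <- numeric(g)
  for (i in seq_len(g)) sig[i] <- stats::sd(m[i, ])
  R <- 0; I <- 0
  for (i in seq_len(g)) for (j in seq_len(g)) if (i != j) {
    R <- R + (sig[i] - sig[j])^2
    if (sig[i] > 0 && sig[j] > 0) {
      rho <- stats::cor(m[i, ], m[j, ])
      I <- I + sig[i] * sig[j] * (1 - rho)
    }
  }
  R <- R / (2 * g * (g - 1))
  I <- I / (g * (g - 1))
  ss <- 0
  for (i in seq_len(g)) for (j in seq_len(e)) {
    ss <- ss + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + mean(m))^2
  }
  c(R = R, I = I, sigma2_GE = ss / ((g - 1) * (e - 1)))
}
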