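#' Per-genotype substrate rank curves
#'
#' For each genotype, substrates are ranked by decreasing relative growth
#' score of that genotype, so every curve is non-increasing along its own
#' rank axis; the substrate at a given rank may differ between genotypes.
#' Increased separation between curves reflects genetic variance; steeper
#' curves reflect environmental variance. Ties are broken by design carbon
#' order, making the output deterministic.
#'
#' @param m A complete `gxe_matrix` (see [build_matrix()]).
#' @return A `rank_curves` data frame with columns `temperature_c, genotype,
#'   rank, carbon, score` and attribute `mode = "per_genotype_rank"`.
#' @export
per_genotype_ranks <- function(m) {
  t_c <- attr(m, "temperature_c")
  if (is.null(t_c)) t_c <- NA_real_
  m <- unclass(m)
  stopifnot(is.matrix(m), !anyNA(m))
  e <- ncol(m)
  rows <- lapply(rownames(m), function(g) {
    ord <- order(-m[g, ], seq_len(e))
    data.frame(temperature_c = t_c, genotype = g, rank = seq_len(e),
               carbon = colnames(m)[ord], score = unname(m[g, ord]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, mode = "per_genotype_rank",
            class = c("rank_curves", "data.frame"))
}

#' Fixed-reference substrate rank curves
#'
#' All genotypes share one substrate order: the order that sorts the scores
#' of the reference genotype - the one with the highest mean score across
#' substrates (ties broken by design genotype order) - decreasingly. In this
#' display unequal slopes between curves reveal responsiveness and crossing
#' curves reveal inconsistency.
#'
#' @param m A complete `gxe_matrix`.
#' @return A `rank_curves` data frame as in [per_genotype_ranks()], with
#'   attributes `mode = "fixed_reference_order"` and `reference` (the
#'   reference genotype label).
#' @export
fixed_reference_ranks <- function(m) {
  t_c <- attr(m, "temperature_c")
  if (is.null(t_c)) t_c <- NA_real_
  m <- unclass(m)
  stopifnot(is.matrix(m), !anyNA(m))
  e <- ncol(m)
  ref <- which.max(rowMeans(m))     # first maximum = design-order tie-break
  ord <- order(-m[ref, ], seq_len(e))
  rows <- lapply(rownames(m), function(g)
    data.frame(temperature_c = t_c, genotype = g, rank = seq_len(e),
               carbon = colnames(m)[ord], score = unname(m[g, ord])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, mode = "fixed_reference_order",
            reference = rownames(m)[ref],
            class = c("rank_curves", "data.frame"))
}

#' Rank curves across all design temperatures
#'
#' @param scores An `ma_scores` table covering the full design.
#' @param mode `"per_genotype"` or `"fixed_reference"`.
#' @param design The [experiment_design()]; defaults to the attached one.
#' @return A `rank_curves` data frame spanning every design temperature.
#' @export
rank_curves <- function(scores, mode = c("per_genotype", "fixed_reference"),
                        design = attr(scores, "design")) {
  mode <- match.arg(mode)
  if (is.null(design))
    stop("no design attached to the score table; pass 'design'",
         call. = FALSE)
  fn <- if (mode == "per_genotype") per_genotype_ranks
        else fixed_reference_ranks
  parts <- lapply(design$temperatures, function(t)
    fn(build_matrix(scores, t, design)))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, mode = attr(parts[[1L]], "mode"),
            class = c("rank_curves", "data.frame"))
}

#' Plot rank curves
#'
#' One panel per temperature; one line per genotype over the substrate rank
#' axis. A quick visual check of genetic separation, responsiveness
#' (slope differences) and inconsistency (crossing lines); the tables, not
#' the plots, are the analysis surface.
#'
#' @param x A `rank_curves` table.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.rank_curves <- function(x, ...) {
  temps <- unique(x$temperature_c)
  genos <- unique(x$genotype)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(temps)),
                       mar = c(3, 3, 2, 0.5), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(old))
  for (t in temps) {
    d <- x[x$temperature_c == t, ]
    m <- matrix(d$score, nrow = max(d$rank),
                dimnames = list(NULL, unique(d$genotype)))
    graphics::matplot(m, type = "l", lty = 1, xlab = "substrate rank",
                      ylab = "relative growth score",
                      main = paste0(format(t), " C"), ...)
    graphics::abline(h = 0, col = "grey", lty = 3)
  }
  invisible(x)
}
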