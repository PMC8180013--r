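MA_CATEGORIES <- c("resource_independent_deleterious",
                   "resource_dependent_deleterious",
                   "non_deleterious")

#' Define a growth-performance loss threshold
#'
#' A loss criterion is a retained fraction of ancestral performance: a
#' genotype has "lost" performance on a substrate when its relative growth
#' score falls strictly below `log10(fraction)`. The three conventional
#' criteria are fractions 0.99, 0.95 and 0.90.
#'
#' @param fraction Retained-performance fraction in (0, 1).
#' @return A `loss_threshold` with fields `label` (e.g. `"0.95"`),
#'   `fraction` and `cutoff = log10(fraction)`.
#' @export
loss_threshold <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction >= 1)
    stop("'fraction' must be a single number in (0, 1)", call. = FALSE)
  label <- if (abs(fraction * 100 - round(fraction * 100)) < 1e-9)
    sprintf("%.2f", fraction) else format(fraction)
  structure(list(label = label, fraction = fraction,
                 cutoff = log10(fraction)),
            class = "loss_threshold")
}

#' Classify one genotype at one temperature
#'
#' Counts the substrates on which the genotype's score is strictly below the
#' loss cutoff and maps the count to a category: below on all E substrates
#' is resource-independent deleterious, below on at least one but not all is
#' resource-dependent deleterious (conditional neutrality), below on none is
#' non-deleterious. A score exactly at the cutoff counts as not lost (strict
#' inequality).
#'
#' @param scores Complete numeric vector of the genotype's scores across the
#'   E substrates.
#' @param threshold A [loss_threshold()].
#' @return A list with `n_substrates_below` and `category`.
#' @export
classify_genotype <- function(scores, threshold) {
  stopifnot(inherits(threshold, "loss_threshold"))
  if (length(scores) < 1L || anyNA(scores))
    stop("scores across substrates must be complete", call. = FALSE)
  e <- length(scores)
  n_below <- sum(scores < threshold$cutoff)
  category <- if (n_below == e) MA_CATEGORIES[1L]
              else if (n_below >= 1L) MA_CATEGORIES[2L]
              else MA_CATEGORIES[3L]
  list(n_substrates_below = n_below, category = category)
}

#' Classify every genotype at every temperature and threshold
#'
#' @param scores An `ma_scores` table covering the full design.
#' @param design The [experiment_design()]; defaults to the attached one.
#' @param thresholds Numeric vector of retained-performance fractions
#'   (default `c(0.99, 0.95, 0.90)`).
#' @return An `ma_classes` data frame with columns `genotype,
#'   temperature_c, threshold, n_substrates_below, category`.
#' @export
classify_scores <- function(scores, design = attr(scores, "design"),
                            thresholds = c(0.99, 0.95, 0.90)) {
  if (is.null(design))
    stop("no design attached to the score table; pass 'design'",
         call. = FALSE)
  ths <- lapply(thresholds, loss_threshold)
  rows <- list()
  for (t in design$temperatures) {
    m <- build_matrix(scores, t, design)
    for (th in ths) {
      for (g in design$genotypes) {
        cl <- classify_genotype(m[g, ], th)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, temperature_c = t, threshold = th$label,
          n_substrates_below = cl$n_substrates_below,
          category = cl$category)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, design = design, class = c("ma_classes", "data.frame"))
}

#' Category counts and proportions per temperature and threshold
#'
#' Tabulates, for each temperature x threshold, how many of the G genotypes
#' fall in each category and the corresponding fractions; the denominator is
#' always all G genotypes.
#'
#' @param classes An `ma_classes` table (one row per genotype per
#'   temperature per threshold; duplicates are an error).
#' @return A data frame with columns `temperature_c, threshold, category,
#'   count, proportion, G`; the three proportions sum to 1 within each
#'   temperature x threshold.
#' @export
category_proportions <- function(classes) {
  stopifnot(is.data.frame(classes))
  if (nrow(classes) == 0L)
    stop("no classification results to tabulate", call. = FALSE)
  split_key <- paste(classes$temperature_c, classes$threshold, sep = "|")
  rows <- lapply(split(classes, split_key), function(d) {
    if (anyDuplicated(d$genotype))
      stop("duplicate genotype ",
           sQuote(d$genotype[duplicated(d$genotype)][1L]),
           " at temperature ", d$temperature_c[1L], ", threshold ",
           d$threshold[1L], call. = FALSE)
    G <- nrow(d)
    counts <- vapply(MA_CATEGORIES, function(k) sum(d$category == k),
                     integer(1))
    data.frame(temperature_c = d$temperature_c[1L],
               threshold = d$threshold[1L],
               category = MA_CATEGORIES,
               count = unname(counts),
               proportion = unname(counts) / G,
               G = G)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$temperature_c,
                   -as.numeric(out$threshold),
                   match(out$category, MA_CATEGORIES)), ]
  rownames(out) <- NULL
  out
}
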