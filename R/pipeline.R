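#' Run the full analysis pipeline on a measurement table
#'
#' Convenience wrapper chaining the pipeline stages: score table, per-
#' temperature variance partition with the responsiveness-inconsistency
#' decomposition, genotype classification under each loss threshold,
#' category proportions, temperature-trend fits for every variance
#' component, and the logistic trend of the resource-dependent proportion
#' for each threshold.
#'
#' @param records Measurement records (see [read_measurements()]).
#' @param design The [experiment_design()].
#' @param thresholds Loss-threshold fractions (default
#'   `c(0.99, 0.95, 0.90)`).
#' @param alpha Significance level for model simplification.
#' @return An `ma_analysis` list with elements `scores`, `components`,
#'   `classes`, `proportions`, `component_trends` and `proportion_trends`
#'   (one `trend_fit_binomial` per threshold, for the
#'   resource-dependent-deleterious category).
#' @export
run_pipeline <- function(records, design, thresholds = c(0.99, 0.95, 0.90),
                         alpha = 0.05) {
  scores <- build_score_table(records, design)
  components <- partition_all(scores, design)
  classes <- classify_scores(scores, design, thresholds)
  proportions <- category_proportions(classes)
  component_trends <- fit_component_trends(components, alpha = alpha)
  dep <- proportions[proportions$category ==
                       "resource_dependent_deleterious", ]
  proportion_trends <- lapply(split(dep, dep$threshold), function(d) {
    d <- d[order(d$temperature_c), ]
    fit_proportion_trend(d$count, d$G, d$temperature_c, alpha = alpha)
  })
  structure(list(scores = scores, components = components,
                 classes = classes, proportions = proportions,
                 component_trends = component_trends,
                 proportion_trends = proportion_trends,
                 design = design),
            class = "ma_analysis")
}

#' @export
print.ma_analysis <- function(x, ...) {
  cat("MA genotype-by-environment analysis\n")
  cat("  scores:", nrow(x$scores), "genotype x carbon x temperature cells\n")
  cat("  variance components by temperature:\n")
  comp <- x$components
  comp[-1] <- signif(comp[-1], 4)
  print(comp, row.names = FALSE)
  share_G <- 100 * mean(x$components$sigma2_G / x$components$total)
  share_R <- 100 * mean(x$components$responsiveness /
                          x$components$sigma2_GE)
  cat(sprintf("  mean genetic share of total variance: %.1f%%\n", share_G))
  cat(sprintf("  mean responsiveness share of G x E variance: %.1f%%\n",
              share_R))
  for (th in names(x$proportion_trends)) {
    f <- x$proportion_trends[[th]]
    if (f$separation)
      cat(sprintf("  resource-dependent trend (loss < log10 %s): sign %d (separated fit)\n",
                  th, f$slope_sign))
    else
      cat(sprintf(
        "  resource-dependent trend (loss < log10 %s): slope %+.4f /C, LR chi2(1) = %.3f, p = %.3g\n",
        th, f$slope, f$lr_chisq, f$p))
  }
  invisible(x)
}
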