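#' Fit a linear-plus-quadratic temperature trend to a variance component
#'
#' Ordinary least squares of a per-temperature quantity on temperature and
#' temperature squared, with marginal (type II) F tests per term, followed
#' by stepwise model simplification: the quadratic term is dropped when
#' non-significant at `alpha` and the model refitted; the linear term is
#' then dropped the same way. When the quadratic term is retained the
#' linear term is kept regardless (marginality). Temperature is centred at
#' its mean before squaring, for conditioning; reported coefficients are
#' back-transformed to the raw Celsius scale, so fitted values are
#' unaffected by the centring.
#'
#' @param values Numeric response, one value per temperature.
#' @param temperatures Assay temperatures (Celsius), length >= 4 so the full
#'   model has a residual degree of freedom.
#' @param alpha Significance level for stepwise removal (default 0.05).
#' @param response Label stored with the fit.
#' @return A `trend_fit` list: `response`; `terms` (full-model type II table
#'   with columns `term, df, statistic, p`); `retained` (named logical for
#'   linear and quadratic); `coefficients` on the raw temperature scale
#'   (`intercept, linear_T, quadratic_T`, zero for dropped terms);
#'   `fitted` values at the input temperatures; `model` (the final `lm`).
#' @export
fit_component_trend <- function(values, temperatures, alpha = 0.05,
                                response = "component") {
  n <- length(values)
  if (n != length(temperatures))
    stop("'values' and 'temperatures' lengths differ", call. = FALSE)
  if (n < 4L)
    stop("at least 4 temperature points are needed for the quadratic model",
         call. = FALSE)
  if (anyNA(values) || anyNA(temperatures))
    stop("missing values in trend input", call. = FALSE)
  ctr <- mean(temperatures)
  # F statistics and p-values are invariant to scaling the response; fitting
  # on a unit scale keeps tiny variance components well conditioned.
  scale <- max(abs(values - mean(values)))
  if (scale == 0) scale <- 1
  d <- data.frame(value = values / scale, t1 = temperatures - ctr)
  d$t2 <- d$t1^2

  full <- stats::lm(value ~ t1 + t2, data = d)
  tab <- marginal_f_table(full)

  p_quad <- tab$p[tab$term == "quadratic_T"]
  retained <- c(linear = TRUE, quadratic = TRUE)
  if (is.na(p_quad) || p_quad >= alpha) {
    retained["quadratic"] <- FALSE
    lin <- stats::lm(value ~ t1, data = d)
    p_lin <- marginal_f_table(lin)$p[1L]
    if (is.na(p_lin) || p_lin >= alpha) {
      retained["linear"] <- FALSE
      model <- stats::lm(value ~ 1, data = d)
    } else model <- lin
  } else model <- full

  cf <- stats::coef(model)
  b0 <- cf["(Intercept)"]
  b1 <- if ("t1" %in% names(cf)) cf[["t1"]] else 0
  b2 <- if ("t2" %in% names(cf)) cf[["t2"]] else 0
  coefficients <- scale * c(intercept = unname(b0) - b1 * ctr + b2 * ctr^2,
                            linear_T = b1 - 2 * b2 * ctr,
                            quadratic_T = b2)

  structure(list(response = response, terms = tab, retained = retained,
                 alpha = alpha, center = ctr,
                 coefficients = coefficients,
                 fitted = scale * unname(stats::fitted(model)),
                 temperatures = temperatures, model = model),
            class = "trend_fit")
}

# Type II (marginal) F table for an lm on centred t1 (+ t2), with readable
# term names. car::Anova refuses exactly-interpolating fits (zero residual
# sum of squares); those fall back to a direct drop-one computation, where a
# term explaining a perfect fit gets F = Inf, p = 0. Degenerate fits (zero
# residual and model SS) yield p = NA.
marginal_f_table <- function(model) {
  a <- tryCatch(car::Anova(model, type = 2), error = function(e) NULL)
  if (!is.null(a)) {
    keep <- rownames(a) != "Residuals"
    term <- rownames(a)[keep]
    term[term == "t1"] <- "linear_T"
    term[term == "t2"] <- "quadratic_T"
    return(data.frame(term = term,
                      df = a$Df[keep],
                      df_residual = a$Df[!keep],
                      statistic = a$`F value`[keep],
                      p = a$`Pr(>F)`[keep]))
  }
  terms_lab <- attr(stats::terms(model), "term.labels")
  mf <- stats::model.frame(model)
  response <- names(mf)[1L]
  rss_full <- sum(stats::residuals(model)^2)
  df_res <- stats::df.residual(model)
  stat <- p <- numeric(length(terms_lab))
  for (i in seq_along(terms_lab)) {
    keep <- setdiff(terms_lab, terms_lab[i])
    f <- stats::reformulate(if (length(keep)) keep else "1",
                            response = response)
    reduced <- stats::lm(f, data = mf)
    ss_term <- sum(stats::residuals(reduced)^2) - rss_full
    if (rss_full > 0) {
      stat[i] <- (ss_term / 1) / (rss_full / df_res)
      p[i] <- stats::pf(stat[i], 1, df_res, lower.tail = FALSE)
    } else if (ss_term > 0) {
      stat[i] <- Inf; p[i] <- 0
    } else {
      stat[i] <- NA_real_; p[i] <- NA_real_
    }
  }
  term <- terms_lab
  term[term == "t1"] <- "linear_T"
  term[term == "t2"] <- "quadratic_T"
  data.frame(term = term, df = 1L, df_residual = df_res,
             statistic = stat, p = p)
}

#' Fit a logistic temperature trend to category counts
#'
#' Binomial generalized linear model (logit link) of per-temperature
#' category counts on temperature, fitted by iteratively reweighted least
#' squares (relative deviance change below 1e-10 or 100 iterations). The
#' trend is summarised by the likelihood-ratio chi-square of the linear
#' model against the intercept-only model (1 df). A quadratic term can be
#' added and is tested the same way against the linear model; with the
#' default `quadratic = TRUE` its result is reported but the returned slope
#' is always the linear model's.
#'
#' When the counts are all zero or all `G`, or the fit is separated (the
#' slope diverges), the fit is flagged and only the slope sign is
#' trustworthy; a warning is emitted.
#'
#' @param successes Per-temperature count of genotypes in the category.
#' @param trials Number of genotypes G (scalar or per-temperature vector).
#' @param temperatures Assay temperatures, length >= 3.
#' @param alpha Significance level used to report whether the quadratic term
#'   improves the model.
#' @param quadratic Whether to also test a quadratic term.
#' @return A `trend_fit_binomial` list: `coefficients` (raw scale:
#'   `intercept, linear_T`), `slope`, `slope_sign`, `lr_chisq`, `df`, `p`,
#'   `separation`, `quadratic_improves`, `quadratic_lr_chisq`,
#'   `quadratic_p`, `fitted` (proportions), `model`.
#' @export
fit_proportion_trend <- function(successes, trials, temperatures,
                                 alpha = 0.05, quadratic = TRUE) {
  n <- length(temperatures)
  if (n < 3L) stop("at least 3 temperature points are needed", call. = FALSE)
  if (length(successes) != n)
    stop("'successes' and 'temperatures' lengths differ", call. = FALSE)
  trials <- rep_len(trials, n)
  if (any(successes < 0) || any(successes > trials))
    stop("counts must satisfy 0 <= successes <= trials", call. = FALSE)

  ctr <- mean(temperatures)
  d <- data.frame(k = successes, n = trials, t1 = temperatures - ctr)
  d$t2 <- d$t1^2
  ctl <- stats::glm.control(epsilon = 1e-10, maxit = 100L)

  degenerate <- all(successes == 0) || all(successes == trials)
  fit <- stats::glm(cbind(k, n - k) ~ t1, family = stats::binomial(),
                    data = d, control = ctl)
  b <- stats::coef(fit)
  separated <- degenerate || !fit$converged || abs(b[["t1"]]) > 15
  lr <- fit$null.deviance - fit$deviance
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)

  quad <- list(improves = NA, lr = NA_real_, p = NA_real_)
  if (quadratic && !degenerate) {
    fit2 <- stats::glm(cbind(k, n - k) ~ t1 + t2,
                       family = stats::binomial(), data = d, control = ctl)
    quad$lr <- fit$deviance - fit2$deviance
    quad$p <- stats::pchisq(quad$lr, df = 1, lower.tail = FALSE)
    quad$improves <- is.finite(quad$p) && quad$p < alpha
  }

  slope <- unname(b[["t1"]])
  if (separated) {
    warning("separated or degenerate counts: slope reported as sign only",
            call. = FALSE)
    slope_sign <- if (degenerate) 0 else sign(slope)
    slope <- NA_real_
  } else slope_sign <- sign(slope)

  structure(list(
    coefficients = c(intercept = unname(b[["(Intercept)"]]) -
                       unname(b[["t1"]]) * ctr,
                     linear_T = unname(b[["t1"]])),
    slope = slope, slope_sign = slope_sign,
    lr_chisq = lr, df = 1L, p = p,
    separation = separated,
    quadratic_improves = quad$improves,
    quadratic_lr_chisq = quad$lr, quadratic_p = quad$p,
    fitted = unname(stats::fitted(fit)),
    temperatures = temperatures, center = ctr, model = fit),
    class = "trend_fit_binomial")
}

#' Temperature trends for all variance components
#'
#' Applies [fit_component_trend()] to each column of a variance-component
#' table and returns one tidy row per model term.
#'
#' @param components Output of [partition_all()].
#' @param alpha Significance level for model simplification.
#' @return A data frame with columns `response, term, estimate, statistic,
#'   df, p, retained`.
#' @export
fit_component_trends <- function(components, alpha = 0.05) {
  resp <- c("total", "sigma2_G", "sigma2_E", "sigma2_GE",
            "responsiveness", "inconsistency")
  rows <- lapply(resp, function(r) {
    f <- fit_component_trend(components[[r]], components$temperature_c,
                             alpha = alpha, response = r)
    data.frame(response = r,
               term = f$terms$term,
               estimate = unname(f$coefficients[c("linear_T",
                                                  "quadratic_T")]),
               statistic = f$terms$statistic,
               df = f$terms$df,
               p = f$terms$p,
               retained = ifelse(f$retained[c("linear", "quadratic")],
                                 "yes", "no"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Temperature trend for", x$response, "\n")
  cat("  retained terms:",
      paste(names(x$retained)[x$retained], collapse = ", "), "\n")
  cat("  coefficients (raw T scale):\n")
  print(signif(x$coefficients, 6))
  cat("  full-model type II tests:\n")
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' @export
print.trend_fit_binomial <- function(x, ...) {
  cat("Logistic temperature trend\n")
  if (x$separation) cat("  [separated fit: slope sign",
                        x$slope_sign, "]\n")
  else cat("  slope:", signif(x$slope, 6), "per degree C\n")
  cat("  LR chi-square (1 df):", signif(x$lr_chisq, 6),
      " p =", format.pval(x$p), "\n")
  if (!is.na(x$quadratic_improves))
    cat("  quadratic term improves fit:", x$quadratic_improves,
        "(LR =", signif(x$quadratic_lr_chisq, 4), ")\n")
  invisible(x)
}
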